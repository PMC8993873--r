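score,stratum,term,beta
charge_af,all,age_per5,0.508
charge_af,all,race_white,0.465
charge_af,all,height_per10,0.248
charge_af,all,weight_per15,0.115
charge_af,all,sbp_per20,0.197
charge_af,all,dbp_per10,-0.101
charge_af,all,smoker,0.359
charge_af,all,bp_treated,0.349
charge_af,all,diabetes,0.237
charge_af,all,heart_failure,0.701
charge_af,all,prior_mi,0.496
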