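score,stratum,term,beta
pce,white_female,ln_age,-29.799
pce,white_female,ln_age_sq,4.884
pce,white_female,ln_tc,13.540
pce,white_female,ln_age_ln_tc,-3.114
pce,white_female,ln_hdl,-13.578
pce,white_female,ln_age_ln_hdl,3.149
pce,white_female,ln_sbp_treated,2.019
pce,white_female,ln_sbp_untreated,1.957
pce,white_female,smoker,7.574
pce,white_female,ln_age_smoker,-1.665
pce,white_female,diabetes,0.661
pce,black_female,ln_age,17.114
pce,black_female,ln_tc,0.940
pce,black_female,ln_hdl,-18.920
pce,black_female,ln_age_ln_hdl,4.475
pce,black_female,ln_sbp_treated,29.291
pce,black_female,ln_age_ln_sbp_treated,-6.432
pce,black_female,ln_sbp_untreated,27.820
pce,black_female,ln_age_ln_sbp_untreated,-6.087
pce,black_female,smoker,0.691
pce,black_female,diabetes,0.874
pce,white_male,ln_age,12.344
pce,white_male,ln_tc,11.853
pce,white_male,ln_age_ln_tc,-2.664
pce,white_male,ln_hdl,-7.990
pce,white_male,ln_age_ln_hdl,1.769
pce,white_male,ln_sbp_treated,1.797
pce,white_male,ln_sbp_untreated,1.764
pce,white_male,smoker,7.837
pce,white_male,ln_age_smoker,-1.795
pce,white_male,diabetes,0.658
pce,black_male,ln_age,2.469
pce,black_male,ln_tc,0.302
pce,black_male,ln_hdl,-0.307
pce,black_male,ln_sbp_treated,1.916
pce,black_male,ln_sbp_untreated,1.809
pce,black_male,smoker,0.549
pce,black_male,diabetes,0.645
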