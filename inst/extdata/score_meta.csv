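score,stratum,mean_lp,s0,horizon_years,age_min,age_max
charge_af,all,12.5815600,0.9718412736,5,46,90
pce,white_female,-29.18,0.9665,10,40,79
pce,black_female,86.61,0.9533,10,40,79
pce,white_male,61.18,0.9144,10,40,79
pce,black_male,19.54,0.8954,10,40,79
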