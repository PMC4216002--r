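sex,b0,b_age,b_age2,b_height2,age_min,age_max,height_min,height_max
male,-0.1933,0.00064,-0.000269,0.00018642,20,85,120,210
female,-0.3560,0.01870,-0.000382,0.00014815,18,85,120,210
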