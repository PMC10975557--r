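sex,age_min,age_max,eer_low_pal,eer_high_pal
male,10,17,2300,3100
female,10,17,2100,2800
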