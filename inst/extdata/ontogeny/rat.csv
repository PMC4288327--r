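life_stage,body_weight,hepatic_fraction_of_adult,gut_fraction_of_adult,mrp2_fraction_of_adult
PND3,0.010,0.0396465953,0.05,0.10
PND10,0.022,0.0412616000,0.10,0.30
PND21,0.055,0.1556510000,0.40,0.70
adult,0.25,1,1,1
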