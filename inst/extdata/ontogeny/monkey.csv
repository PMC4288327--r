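life_stage,body_weight,hepatic_fraction_of_adult,gut_fraction_of_adult,mrp2_fraction_of_adult
PND5,0.5,0.3774102850,0.5346,1
PND35,0.75,0.3771720000,0.70,1
PND70,1.0,0.4128026500,0.85,1
adult,5.0,1,1,1
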