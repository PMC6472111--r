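"name","protein","fat","carbohydrate","ash","whey_share_of_protein","energy_density","calibrated"
"skimmed_milk",0.37975,0.01,0.464866666666666,0.08,0.2,14.78635,TRUE
"whey_protein_concentrate",0.732375,0.0672999999999996,0.14,0.0536,1,17.320475,TRUE
"lactose",0,0,1,0,0,17,FALSE
"vegetable_oil",0,1,0,0,0,37,FALSE
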