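mass_fraction: 0.02
additive_efs:
  riboflavin: 67.0
  cyanocobalamin: 4.8
  ergocalciferol: 4.8
  potassium_carbonate: 0.3
  feed_vitamin_mix: 1.1
  ascorbic_acid: 3.1
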