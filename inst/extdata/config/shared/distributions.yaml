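raw_milk_ef:
  family: normal_cv
  cv: 20.0
oil_ef:
  family: lognormal_cv
  cv: 25.0
electricity_use:
  family: triangular
  rel_min: -0.5
  rel_max: 0.8
  centre: mean
heat_use:
  family: triangular
  rel_min: -0.3
  rel_max: 0.6
  centre: mean
sterilisation_water:
  family: triangular
  rel_min: -0.5
  rel_max: 0.5
  centre: mode
stove_efficiency:
  family: triangular
  rel_min: -0.15
  rel_max: 0.15
  centre: mode
food_ef:
  family: lognormal_cv
  cv: 45.0
cooking_energy:
  family: triangular
  rel_min: -0.3
  rel_max: 3.0
  centre: mean
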