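infant_energy_per_day: 2480.0
feeds_per_day: 6.0
serving_mass: 18.6
bms_energy_density: 21.7
water_per_bottle: 0.13
sterilisation_water: 5.0
bottles_per_batch: 6.0
bottles_per_period: 6.0
period_days: 184.0
maternal_extra_energy: 500.0
period_total_food: 385.0
period_bms_mass: 21.0
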