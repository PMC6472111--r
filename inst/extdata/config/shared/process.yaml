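milk_composition:
  fat: 0.0225
  protein: 0.0285
  lactose: 0.060381576941
  ash: 0.003
  whey_protein_share: 0.23
  skim_fat_dm_fraction: 0.01
  calibrated: yes
whey_split:
  fat_to_whey: 0.9
  lactose_to_whey: 0.704458686607
  ash_to_whey: 0.85
  calibrated: yes
cream_dm_content: 0.45
curd_dm_content: 0.45
whey_dm_content: 0.065
permeate_dm_content: 0.05
energy_coefficients:
  fat: 37.0
  protein: 17.0
  carbohydrate: 17.0
  ash: 0.0
step_energy:
  wet_mix_spray_dry:
    electricity: 1.6
    heat: 7.2
    per: kg_bms
  whey_separation:
    electricity: 1.261598161414
    heat: 3.784794484242
    per: kg_whey_dm
  cheese_making:
    electricity: 0.267500667317
    heat: 0.222917222764
    per: kg_cheese_skim_dm
  skimming:
    electricity: 0.010948905109
    heat: 0.021897810219
    per: kg_raw_milk
  calibrated: yes
prices:
  skim_milk: 2.2
  cream: 4.5
  cheese_curd: 5.0
  whey: 0.45
  whey_protein_concentrate: 7.5
  lactose: 0.7
  permeate: 0.15
  calibrated: yes
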