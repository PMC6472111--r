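country: United Kingdom
role: consumption
consumption:
  production_country: France
  stove_profile:
    gas:
      share: 0.65
      ef:
        value: 0.065
        unit: kg CO2e per MJ fuel
        gas_shares:
          co2: 0.95
          ch4: 0.05
          n2o: 0.0
        calibrated: no
      efficiency: 0.35
    electricity:
      share: 0.35
      ef:
        value: 0.085517032471
        unit: kg CO2e per MJ fuel
        gas_shares:
          co2: 0.95
          ch4: 0.05
          n2o: 0.0
        calibrated: yes
      efficiency: 0.75
  sterilisation_boil_factor: 1.0
  steam_steriliser_factor: 0.14
  ambient_temp_c: 20.0
  cooking_heat_mj_per_kg: 1.3
  retail_transport_legs:
  - mode: road
    distance_km: 1200.0
    ef: 0.113430127042
    mass_kg: 1.102
    calibrated: yes
  bottle:
    mass_kg: 0.1
    ef: 1.75
  bms_waste_fraction:
    value: 0.137571869011
    calibrated: yes
  diet:
    items:
    - name: wheat
      category: plant
      share: 0.28
      ef_per_mj:
        value: 0.049933582059
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.27846
      luc_commodity: ''
    - name: potatoes
      category: plant
      share: 0.05
      ef_per_mj:
        value: 0.033289054706
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.891072
      luc_commodity: ''
    - name: sugar
      category: plant
      share: 0.09
      ef_per_mj:
        value: 0.058255845735
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.1642914
      luc_commodity: ''
    - name: vegetable oils
      category: plant
      share: 0.11
      ef_per_mj:
        value: 0.199734328235
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.0751842
      luc_commodity: ''
    - name: fruit and vegetables
      category: plant
      share: 0.09
      ef_per_mj:
        value: 0.166445273529
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 1.67076
      luc_commodity: ''
    - name: rice
      category: plant
      share: 0.02
      ef_per_mj:
        value: 0.216378855588
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.55692
      luc_commodity: ''
    - name: other cereals
      category: plant
      share: 0.04
      ef_per_mj:
        value: 0.049933582059
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.27846
      luc_commodity: ''
    - name: milk
      category: animal
      share: 0.08
      ef_per_mj:
        value: 0.519217695194
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 1.030302
      luc_commodity: ''
    - name: cheese
      category: animal
      share: 0.05
      ef_per_mj:
        value: 0.519217695194
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.27846
      luc_commodity: ''
    - name: beef
      category: animal
      share: 0.02
      ef_per_mj:
        value: 2.487918122807
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.27846
      luc_commodity: ''
    - name: lamb
      category: animal
      share: 0.015
      ef_per_mj:
        value: 2.487918122807
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.27846
      luc_commodity: ''
    - name: pork
      category: animal
      share: 0.05
      ef_per_mj:
        value: 0.59493694241
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.250614
      luc_commodity: ''
    - name: poultry
      category: animal
      share: 0.06
      ef_per_mj:
        value: 0.378596236079
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.348075
      luc_commodity: ''
    - name: eggs
      category: animal
      share: 0.02
      ef_per_mj:
        value: 0.324511059497
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.4343976
      luc_commodity: ''
    - name: fish
      category: animal
      share: 0.025
      ef_per_mj:
        value: 0.486766589245
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.137571869011
      mass_per_mj: 0.55692
      luc_commodity: ''
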