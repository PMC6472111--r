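country: China
role: consumption
consumption:
  production_country: New Zealand
  stove_profile:
    coal:
      share: 0.23
      ef:
        value: 0.112
        unit: kg CO2e per MJ fuel
        gas_shares:
          co2: 0.95
          ch4: 0.05
          n2o: 0.0
        calibrated: no
      efficiency: 0.27
    gas:
      share: 0.37
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
      share: 0.4
      ef:
        value: 0.162685260902
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
  - mode: sea
    distance_km: 18000.0
    ef: 0.008
    mass_kg: 1.102
    calibrated: no
  - mode: road
    distance_km: 500.0
    ef: 0.074976406534
    mass_kg: 1.102
    calibrated: yes
  bottle:
    mass_kg: 0.1
    ef: 1.75
  bms_waste_fraction:
    value: 0.140495867769
    calibrated: yes
  diet:
    items:
    - name: rice
      category: plant
      share: 0.3
      ef_per_mj:
        value: 0.201073823844
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.462929453605
      luc_commodity: ''
    - name: wheat
      category: plant
      share: 0.2
      ef_per_mj:
        value: 0.046401651656
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.231464726802
      luc_commodity: ''
    - name: vegetable oils
      category: plant
      share: 0.1
      ef_per_mj:
        value: 0.185606606625
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.062495476237
      luc_commodity: ''
    - name: vegetables
      category: plant
      share: 0.08
      ef_per_mj:
        value: 0.12373773775
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 1.620253087617
      luc_commodity: ''
    - name: sugar
      category: plant
      share: 0.03
      ef_per_mj:
        value: 0.054135260266
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.136564188813
      luc_commodity: ''
    - name: other plant foods
      category: plant
      share: 0.06
      ef_per_mj:
        value: 0.061868868875
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.462929453605
      luc_commodity: ''
    - name: pork
      category: animal
      share: 0.1
      ef_per_mj:
        value: 0.688883066981
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.208318254122
      luc_commodity: ''
    - name: dairy
      category: animal
      share: 0.02
      ef_per_mj:
        value: 0.601207040274
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.856419489169
      luc_commodity: ''
    - name: poultry
      category: animal
      share: 0.04
      ef_per_mj:
        value: 0.438380133533
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.289330908503
      luc_commodity: ''
    - name: eggs
      category: animal
      share: 0.04
      ef_per_mj:
        value: 0.375754400171
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.361084973812
      luc_commodity: ''
    - name: fish
      category: animal
      share: 0.03
      ef_per_mj:
        value: 0.563631600257
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.140495867769
      mass_per_mj: 0.462929453605
      luc_commodity: ''
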