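country: Vietnam
role: consumption
consumption:
  production_country: France
  stove_profile:
    wood:
      share: 0.4
      ef:
        value: 0.008
        unit: kg CO2e per MJ fuel
        gas_shares:
          co2: 0.95
          ch4: 0.05
          n2o: 0.0
        calibrated: no
      efficiency: 0.13
    lpg:
      share: 0.35
      ef:
        value: 0.0715
        unit: kg CO2e per MJ fuel
        gas_shares:
          co2: 0.95
          ch4: 0.05
          n2o: 0.0
        calibrated: no
      efficiency: 0.5
    electricity:
      share: 0.25
      ef:
        value: 0.134468774017
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
    distance_km: 21000.0
    ef: 0.008
    mass_kg: 1.102
    calibrated: no
  - mode: road
    distance_km: 700.0
    ef: 0.110012963443
    mass_kg: 1.102
    calibrated: yes
  bottle:
    mass_kg: 0.1
    ef: 1.75
  bms_waste_fraction:
    value: 0.025974025974
    calibrated: yes
  diet:
    items:
    - name: rice
      category: plant
      share: 0.5
      ef_per_mj:
        value: 0.207173002656
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.455698153727
      luc_commodity: ''
    - name: wheat
      category: plant
      share: 0.03
      ef_per_mj:
        value: 0.047809154459
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.227849076864
      luc_commodity: ''
    - name: vegetable oils
      category: plant
      share: 0.05
      ef_per_mj:
        value: 0.191236617836
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.061519250753
      luc_commodity: ''
    - name: vegetables
      category: plant
      share: 0.06
      ef_per_mj:
        value: 0.127491078558
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 1.594943538046
      luc_commodity: ''
    - name: sugar
      category: plant
      share: 0.04
      ef_per_mj:
        value: 0.055777346869
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.13443095535
      luc_commodity: ''
    - name: other plant foods
      category: plant
      share: 0.04
      ef_per_mj:
        value: 0.063745539279
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.55
          ch4: 0.05
          n2o: 0.4
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.455698153727
      luc_commodity: ''
    - name: pork
      category: animal
      share: 0.12
      ef_per_mj:
        value: 0.534065934066
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.205064169177
      luc_commodity: ''
    - name: poultry
      category: animal
      share: 0.05
      ef_per_mj:
        value: 0.33986013986
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.28481134608
      luc_commodity: ''
    - name: fish
      category: animal
      share: 0.06
      ef_per_mj:
        value: 0.436963036963
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.455698153727
      luc_commodity: ''
    - name: eggs
      category: animal
      share: 0.025
      ef_per_mj:
        value: 0.291308691309
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.355444559907
      luc_commodity: ''
    - name: dairy
      category: animal
      share: 0.025
      ef_per_mj:
        value: 0.466093906094
        unit: kg CO2e per MJ food
        gas_shares:
          co2: 0.3
          ch4: 0.45
          n2o: 0.25
        distribution:
          family: lognormal_cv
          cv: 45.0
        calibrated: yes
      household_waste: 0.025974025974
      mass_per_mj: 0.843041584396
      luc_commodity: ''
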