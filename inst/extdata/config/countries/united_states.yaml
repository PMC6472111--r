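country: United States
role: production
production:
  raw_milk_ef:
    value: 0.73
    unit: kg CO2e per kg ECM
    gas_shares:
      co2: 0.25
      ch4: 0.67
      n2o: 0.08
    distribution:
      family: normal_cv
      cv: 20.0
  milk_density: 1.035
  milk_meat_allocation: 0.9
  electricity_ef:
    value: 0.14
    unit: kg CO2e per MJ electricity
    gas_shares:
      co2: 0.95
      ch4: 0.05
      n2o: 0.0
    calibrated: yes
  heat_ef:
    value: 0.065007106147
    unit: kg CO2e per MJ heat
    gas_shares:
      co2: 0.95
      ch4: 0.05
      n2o: 0.0
    calibrated: yes
  oil_blend:
    palm: 0.161764705882
    soybean: 0.55
    rapeseed: 0.138235294118
    sunflower: 0.15
  oil_efs:
    palm:
      value: 2.3
      unit: kg CO2e per kg oil
      gas_shares:
        co2: 0.55
        ch4: 0.05
        n2o: 0.4
      distribution:
        family: lognormal_cv
        cv: 25.0
    soybean:
      value: 1.9
      unit: kg CO2e per kg oil
      gas_shares:
        co2: 0.55
        ch4: 0.05
        n2o: 0.4
      distribution:
        family: lognormal_cv
        cv: 25.0
    rapeseed:
      value: 1.45
      unit: kg CO2e per kg oil
      gas_shares:
        co2: 0.55
        ch4: 0.05
        n2o: 0.4
      distribution:
        family: lognormal_cv
        cv: 25.0
    sunflower:
      value: 1.35
      unit: kg CO2e per kg oil
      gas_shares:
        co2: 0.55
        ch4: 0.05
        n2o: 0.4
      distribution:
        family: lognormal_cv
        cv: 25.0
  oil_sea_distance_km: 2500.0
  sea_transport_ef:
    value: 0.008
    unit: kg CO2e per tonne km
    gas_shares:
      co2: 1.0
      ch4: 0.0
      n2o: 0.0
  packaging_mix:
    tin_can: 0.7
    bag_in_box: 0.3
  packaging_masses:
    tin_can: 0.12
    bag_in_box: 0.06
  packaging_efs:
    tin_can:
      value: 2.8
      unit: kg CO2e per kg packaging material
      gas_shares:
        co2: 1.0
        ch4: 0.0
        n2o: 0.0
      calibrated: yes
    bag_in_box:
      value: 1.5
      unit: kg CO2e per kg packaging material
      gas_shares:
        co2: 1.0
        ch4: 0.0
        n2o: 0.0
      calibrated: yes
  transport_legs:
  - name: raw milk farm to plant
    mode: lorry
    mass_basis: raw_milk
    distance_km: 100.0
    ef: 0.22903232254
    refrigerated: yes
    calibrated: yes
  - name: whey to refining plant
    mode: lorry
    mass_basis: whey
    distance_km: 100.0
    ef: 0.22903232254
    refrigerated: yes
    calibrated: yes
  - name: dry ingredients to BMS plant
    mode: lorry
    mass_basis: dry_ingredients
    distance_km: 100.0
    ef: 0.1
    refrigerated: no
  chain_waste:
  - 0.012345679
  luc_factors:
    palm: 0.4
    soybean: 0.48
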