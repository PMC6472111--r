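# Breastfeeding equivalence and the comparison with BMS consumption.

test_that("equivalent food energy is period food over period BMS mass", {
  p <- feeding_parameters()
  expect_equal(equivalent_food_energy(p), 385 / 21)
  expect_equal(round(equivalent_food_energy(p)), 18)
  p$period_total_food <- 0
  expect_equal(equivalent_food_energy(p), 0)
  p$period_total_food <- 385 / 2
  expect_equal(equivalent_food_energy(p), 385 / 42)
  p$period_bms_mass <- 0
  expect_error(equivalent_food_energy(p), "positive")
})

test_that("diet tables reproduce the reported per-MJ and per-kg values", {
  expected <- list(
    "United Kingdom" = c(plant = "0.074", animal = "0.26", cooking = "0.10",
                         total = "0.44", per_kg = "6.9"),
    "China" = c(plant = "0.12", animal = "0.15", cooking = "0.14",
                total = "0.41", per_kg = "6.5"),
    "Brazil" = c(plant = "0.082", animal = "0.27", cooking = "0.10",
                 total = "0.45", per_kg = "7.8"),
    "Vietnam" = c(plant = "0.13", animal = "0.13", cooking = "0.070",
                  total = "0.33", per_kg = "5.9"))
  for (nm in consumption_countries) {
    bf <- cfp_breastfeeding(scenarios_cache()[[nm]])
    got <- c(plant = format_sig(bf$plant), animal = format_sig(bf$animal),
             cooking = format_sig(bf$cooking), total = format_sig(bf$total),
             per_kg = format_sig(bf$per_kg_bms))
    expect_equal(got, expected[[nm]], label = nm)
  }
})

test_that("a wheat-only diet costs about 0.03 kg CO2e per MJ to produce", {
  diet <- list(items = list(list(
    name = "wheat", category = "plant", share = 1,
    ef_per_mj = emission_factor(0.03, "kg CO2e per MJ food"),
    household_waste = 0, mass_per_mj = 0.1, luc_commodity = "")))
  prof <- scenarios_cache()[["United Kingdom"]]$consumption$stove_profile
  res <- diet_cfp(diet, prof)
  expect_equal(res$plant, 0.03, tolerance = 1e-9)
  expect_equal(res$animal, 0)
  # zero-EF single item with no cooking mass gives exactly zero
  diet0 <- list(items = list(list(
    name = "x", category = "plant", share = 1,
    ef_per_mj = emission_factor(0), household_waste = 0,
    mass_per_mj = 0, luc_commodity = "")))
  expect_equal(diet_cfp(diet0, prof)$total, 0)
})

test_that("household waste inflates the production term", {
  prof <- scenarios_cache()[["United Kingdom"]]$consumption$stove_profile
  mk <- function(hw) list(items = list(list(
    name = "wheat", category = "plant", share = 1,
    ef_per_mj = emission_factor(0.03), household_waste = hw,
    mass_per_mj = 0, luc_commodity = "")))
  expect_equal(diet_cfp(mk(0.5), prof)$plant,
               2 * diet_cfp(mk(0), prof)$plant)
})

test_that("BMS waste reduces the breastmilk needed per kg of powder", {
  s <- scenarios_cache()[["United Kingdom"]]
  bf0 <- cfp_breastfeeding(s, bms_waste_fraction = 0)
  bf9 <- cfp_breastfeeding(s, bms_waste_fraction = 0.9)
  expect_equal(bf9$per_kg_bms, 0.1 * bf0$per_kg_bms, tolerance = 1e-9)
  expect_equal(bf0$per_kg_bms, bf0$total * 385 / 21, tolerance = 1e-9)
})

test_that("feeding BMS exceeds breastfeeding in every default country", {
  for (nm in consumption_countries) {
    s <- scenarios_cache()[[nm]]
    det <- cfp_consumption(s, cfp_production(paired_production(nm)))
    cmp <- compare_footprints(det, cfp_breastfeeding(s))
    expect_gt(cmp$difference, 0)
    expect_lt(cmp$ratio, 1)
  }
})

test_that("breastfeeding is 40-53% lower within 3 points of reported values", {
  reported <- c("United Kingdom" = 40, "China" = 53, "Brazil" = 43,
                "Vietnam" = 46)
  for (nm in consumption_countries) {
    s <- scenarios_cache()[[nm]]
    det <- cfp_consumption(s, cfp_production(paired_production(nm)))
    bf <- cfp_breastfeeding(s)
    red <- 100 * (1 - bf$per_kg_bms / total_cfp(det))
    expect_lt(abs(red - reported[[nm]]), 3, label = nm)
  }
})

test_that("identical totals give zero difference and unit ratio", {
  s <- scenarios_cache()[["China"]]
  det <- cfp_consumption(s, cfp_production(paired_production("China")))
  bf <- cfp_breastfeeding(s)
  bf$per_kg_bms <- total_cfp(det)
  cmp <- compare_footprints(det, bf)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$ratio, 1)
})

test_that("mismatched GWP sets cannot be compared", {
  s <- scenarios_cache()[["China"]]
  det <- cfp_consumption(s, cfp_production(paired_production("China")))
  bf <- cfp_breastfeeding(s, gwp = "AR5")
  expect_error(compare_footprints(det, bf), "GWP")
})

test_that("the waste sweep is monotone: CFP_BF strictly decreasing, CFP_Cons flat", {
  for (nm in c("United Kingdom", "China")) {
    s <- scenarios_cache()[[nm]]
    sw <- waste_sweep(s, cfp_production(paired_production(nm)),
                      waste_grid = seq(0, 0.6, by = 0.05))
    expect_true(all(diff(sw$cfp_bf) < 0))
    expect_true(all(diff(sw$cfp_cons) == 0))
    expect_true(all(diff(sw$ratio) < 0))
  }
})

test_that("LUC raises CFP_Cons by 0.5-0.7% and doubles the Brazil diet", {
  for (nm in consumption_countries) {
    s <- scenarios_cache()[[nm]]
    ps <- paired_production(nm)
    base <- total_cfp(cfp_consumption(s, cfp_production(ps)))
    luc <- total_cfp(cfp_consumption(s,
             cfp_production(scenario_variant(ps, "include_luc"))))
    pct <- 100 * (luc - base) / base
    expect_true(pct >= 0.5 && pct <= 0.7, label = nm)
    bf0 <- cfp_breastfeeding(s)
    bf1 <- cfp_breastfeeding(s, include_luc = TRUE)
    ratio <- bf1$per_kg_bms / bf0$per_kg_bms
    if (nm == "Brazil") {
      expect_equal(ratio, 2, tolerance = 0.15)
    } else {
      expect_lte(ratio, 1.02)
    }
  }
})
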