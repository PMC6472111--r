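# Feeding plan and cradle-to-bottle consumption footprint.

test_that("feeding plan arithmetic from the default parameters", {
  plan <- feeding_plan(feeding_parameters())
  expect_equal(plan$servings_per_kg, 54)
  expect_equal(plan$bottles_to_sterilise_per_kg, 54)
  expect_equal(plan$sterilisation_batches_per_kg, 9)
  expect_equal(plan$water_heated_for_prep, 54 * 0.13)
  expect_equal(plan$water_heated_for_sterilisation, 45)
  expect_equal(round_half_up(plan$bottles_manufactured_per_kg, 1), 0.3)
})

test_that("degenerate feeding parameters are rejected", {
  expect_error(feeding_parameters(serving_mass = 0), "positive")
  expect_error(feeding_parameters(serving_mass = 30),
               "inconsistent")  # serving energy drifts beyond 3%
  p <- feeding_parameters()
  p$serving_mass <- 1000
  expect_equal(feeding_plan(p)$servings_per_kg, 1)
})

test_that("home energy scales linearly in water volume and inversely in efficiency", {
  plan <- feeding_plan()
  prof <- scenarios_cache()[["China"]]$consumption$stove_profile
  h1 <- home_energy_cfp(plan, prof)
  plan2 <- plan
  plan2$water_heated_for_sterilisation <- 2 * plan$water_heated_for_sterilisation
  h2 <- home_energy_cfp(plan2, prof)
  expect_equal(h2$sterilisation, 2 * h1$sterilisation)
  expect_equal(h2$preparation, h1$preparation)
  h3 <- home_energy_cfp(plan, prof, mult = list(stove_efficiency = 2))
  expect_equal(h3$sterilisation, h1$sterilisation / 2)
  zero <- lapply(prof, function(f) { f$ef$value <- 0; f })
  h0 <- home_energy_cfp(plan, zero)
  expect_equal(h0$sterilisation, 0)
  expect_equal(h0$preparation, 0)
})

test_that("consumption stage tables reproduce the reported values at 2 s.f.", {
  expected <- list(
    "United Kingdom" = c(bms_production = "8.4", sterilisation = "2.4",
                         preparation = "0.38", transport = "0.15",
                         bottle_production = "0.050", total = "11"),
    "China" = c(bms_production = "9.2", sterilisation = "3.8",
                preparation = "0.59", transport = "0.20",
                bottle_production = "0.050", total = "14"),
    "Brazil" = c(bms_production = "11", sterilisation = "2.2",
                 preparation = "0.33", transport = "0.090",
                 bottle_production = "0.050", total = "14"),
    "Vietnam" = c(bms_production = "8.4", sterilisation = "1.8",
                  preparation = "0.28", transport = "0.27",
                  bottle_production = "0.050", total = "11"))
  for (nm in consumption_countries) {
    s <- scenarios_cache()[[nm]]
    det <- cfp_consumption(s, cfp_production(paired_production(nm)))
    got <- c(format_sig(stages(det)), total = format_sig(total_cfp(det)))
    names(got) <- c(names(stages(det)), "total")
    expect_equal(got[names(expected[[nm]])], expected[[nm]], label = nm)
  }
})

test_that("a missing paired production result is an error", {
  s <- scenarios_cache()[["United Kingdom"]]
  expect_error(cfp_consumption(s, NULL), "production")
  expect_error(cfp_consumption(scenarios_cache()[["New Zealand"]], 9.2),
               "consumption role")
})

test_that("sterilisation modes scale the sterilisation stage", {
  s <- scenarios_cache()[["China"]]
  pr <- cfp_production(paired_production("China"))
  stovetop <- cfp_consumption(s, pr)
  none <- cfp_consumption(s, pr, sterilisation_mode = "none")
  steam <- cfp_consumption(s, pr, sterilisation_mode = "steam")
  expect_equal(stages(none)[["sterilisation"]], 0)
  expect_lt(stages(steam)[["sterilisation"]],
            stages(stovetop)[["sterilisation"]])
  expect_equal(stages(none)[["preparation"]],
               stages(stovetop)[["preparation"]])
})

test_that("no-sterilisation reductions span 16-27% with the maximum in China", {
  reds <- vapply(consumption_countries, function(nm) {
    s <- scenarios_cache()[[nm]]
    pr <- cfp_production(paired_production(nm))
    full <- total_cfp(cfp_consumption(s, pr))
    none <- total_cfp(cfp_consumption(s, pr, sterilisation_mode = "none"))
    100 * (full - none) / full
  }, numeric(1))
  expect_true(all(round(reds) >= 16 & round(reds) <= 27))
  expect_equal(names(which.max(reds)), "China")
  expect_equal(round(max(reds)), 27)
})

test_that("steam sterilisation lowers CFP_Cons by 14-23%", {
  reds <- vapply(consumption_countries, function(nm) {
    s <- scenarios_cache()[[nm]]
    pr <- cfp_production(paired_production(nm))
    full <- total_cfp(cfp_consumption(s, pr))
    steam <- total_cfp(cfp_consumption(s, pr, sterilisation_mode = "steam"))
    100 * (full - steam) / full
  }, numeric(1))
  expect_true(all(round(reds) >= 14 & round(reds) <= 23))
})

test_that("consumption-phase share is 19-33% and bottles+transport at most 3%", {
  for (nm in consumption_countries) {
    s <- scenarios_cache()[[nm]]
    det <- cfp_consumption(s, cfp_production(paired_production(nm)))
    v <- stages(det)
    post <- sum(v) - v[["bms_production"]]
    share_pct <- round(100 * post / sum(v))
    expect_true(share_pct >= 19 && share_pct <= 33, label = nm)
    small <- 100 * (v[["transport"]] + v[["bottle_production"]]) / sum(v)
    expect_lte(small, 3)
    expect_gte(small, 1)
  }
})

test_that("mismatched GWP sets between production and consumption error", {
  s <- scenarios_cache()[["China"]]
  pr <- cfp_production(paired_production("China"), gwp = "AR5")
  expect_error(cfp_consumption(s, pr, gwp = "AR4"), "GWP")
})
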