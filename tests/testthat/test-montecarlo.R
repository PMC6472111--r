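# Monte Carlo propagation, OAT sensitivity, scenario switches.

test_that("an all-point specification collapses to the deterministic value", {
  s <- scenarios_cache()[["New Zealand"]]
  specs <- stats::setNames(
    lapply(bmslca:::MC_PARAMETERS, function(p) dist_spec("point")),
    bmslca:::MC_PARAMETERS)
  mc <- monte_carlo(s, n = 50, seed = 1, mode = "production",
                    param_specs = specs)
  det <- total_cfp(cfp_production(s))
  tot <- mc$summary[mc$summary$output == "total", ]
  expect_equal(tot$mean, det, tolerance = 1e-12)
  expect_equal(tot$sd, 0)
})

test_that("unknown parameter names error before sampling", {
  s <- scenarios_cache()[["New Zealand"]]
  expect_error(monte_carlo(s, n = 10, seed = 1,
                           param_specs = list(bogus = dist_spec("point"))),
               "unknown Monte Carlo parameter")
})

test_that("identical seed and spec give bit-identical summaries", {
  s <- scenarios_cache()[["China"]]
  m1 <- monte_carlo(s, n = 500, seed = 123, mode = "comparison")
  m2 <- monte_carlo(s, n = 500, seed = 123, mode = "comparison")
  expect_identical(m1$summary, m2$summary)
  expect_identical(m1$exceedance_probability, m2$exceedance_probability)
  m3 <- monte_carlo(s, n = 500, seed = 124, mode = "comparison")
  expect_false(identical(m1$summary, m3$summary))
})

test_that("single-parameter propagation matches the linear oracle", {
  # a normal CV on the raw-milk EF alone propagates to an output CV equal
  # to the input CV times the raw-milk stage share (stage is linear in EF)
  s <- scenarios_cache()[["New Zealand"]]
  specs <- list(raw_milk_ef = dist_spec("normal_cv", cv = 20))
  mc <- monte_carlo(s, n = 4e4, seed = 9, mode = "production",
                    param_specs = specs)
  det <- cfp_production(s)
  share <- stages(det)[["raw_milk"]] / total_cfp(det)
  tot <- mc$summary[mc$summary$output == "total", ]
  expect_equal(tot$sd / tot$point, 0.20 * share, tolerance = 0.01)
})

test_that("Monte Carlo means converge to deterministic values under the packaged spec", {
  s <- scenarios_cache()[["New Zealand"]]
  mc <- monte_carlo(s, n = 3e4, seed = 17, mode = "production")
  sm <- mc$summary
  for (nm in c("raw_milk", "vegetable_oils", "total")) {
    row <- sm[sm$output == nm, ]
    expect_equal(row$mean, row$point, tolerance = 0.02, label = nm)
  }
})

test_that("total SDs reproduce the reported uncertainties at printed precision", {
  # printed +/- values define a rounding interval of half a unit in their
  # last printed digit; the computed SD must fall inside it
  prod_sd <- c("New Zealand" = 1.4, "United States" = 1.0, "Brazil" = 2,
               "France" = 1.3)
  prod_halfunit <- c(0.05, 0.05, 0.5, 0.05)
  for (i in seq_along(prod_sd)) {
    nm <- names(prod_sd)[i]
    mc <- monte_carlo(scenarios_cache()[[nm]], n = 1e4, seed = 7,
                      mode = "production")
    got <- mc$summary$sd[mc$summary$output == "total"]
    expect_lt(abs(got - prod_sd[[nm]]), prod_halfunit[i] + 1e-9, label = nm)
  }
  cons_sd <- c("United Kingdom" = 1, "China" = 2, "Brazil" = 2,
               "Vietnam" = 1)
  for (nm in consumption_countries) {
    mc <- monte_carlo(scenarios_cache()[[nm]], n = 1e4, seed = 7,
                      mode = "consumption")
    got <- mc$summary$sd[mc$summary$output == "total"]
    expect_lt(abs(got - cons_sd[[nm]]), 0.5, label = nm)
  }
})

test_that("OAT raw-milk elasticity equals the stage share (analytic oracle)", {
  for (nm in c("New Zealand", "Brazil")) {
    s <- scenarios_cache()[[nm]]
    det <- cfp_production(s)
    share <- stages(det)[["raw_milk"]] / total_cfp(det)
    oat <- oat_sensitivity(s, parameters = "raw_milk_ef",
                           target = "production")
    expect_equal(oat$pct_change_high, 10 * share, tolerance = 1e-9)
    expect_equal(oat$pct_change_low, -10 * share, tolerance = 1e-9)
  }
})

test_that("parameters outside the model report zero change", {
  s <- scenarios_cache()[["New Zealand"]]
  s$production$chain_waste <- numeric()  # nothing to perturb
  oat <- oat_sensitivity(s, parameters = "chain_waste", target = "production")
  expect_equal(oat$pct_change_high, 0)
})

test_that("China consumption OAT: stove efficiency and serving mass move 2-3%", {
  s <- scenarios_cache()[["China"]]
  oat <- oat_sensitivity(s, parameters = c("stove_efficiency",
                                           "serving_mass",
                                           "sterilisation_water"),
                         target = "consumption")
  eff <- abs(oat$pct_change_high[oat$parameter == "stove_efficiency"])
  srv <- abs(oat$pct_change_high[oat$parameter == "serving_mass"])
  expect_true(round(eff) %in% 2:3)
  expect_true(round(srv) %in% 2:3)
  expect_error(oat_sensitivity(s, parameters = "nonsense"), "unknown OAT")
  expect_error(oat_sensitivity(s, perturbation = -1), "perturbation")
})

test_that("identity switch leaves pipeline outputs unchanged", {
  s <- scenarios_cache()[["New Zealand"]]
  v <- scenario_variant(s, "identity")
  expect_equal(v, s)
  expect_equal(stages(cfp_production(v)), stages(cfp_production(s)))
  expect_error(scenario_variant(s, "warp_drive"), "unknown scenario switch")
})

test_that("vitamin add-on spans 0.006 to 1.3 kg CO2e per kg BMS", {
  s <- scenarios_cache()[["New Zealand"]]
  efs <- unlist(vitamin_config()$additive_efs)
  base <- total_cfp(cfp_production(s))
  lo <- total_cfp(cfp_production(scenario_variant(s, "vitamins",
                                                  vitamin_ef = min(efs))))
  hi <- total_cfp(cfp_production(scenario_variant(s, "vitamins",
                                                  vitamin_ef = max(efs))))
  expect_equal(lo - base, 0.006, tolerance = 1e-9)
  expect_equal(format_sig(hi - base), "1.3")
})

test_that("AR4 to AR5 re-characterisation raises CFP_Cons by 4-5%", {
  for (nm in consumption_countries) {
    s <- scenarios_cache()[[nm]]
    ps <- paired_production(nm)
    base <- total_cfp(cfp_consumption(s, cfp_production(ps)))
    v <- scenario_variant(s, "gwp_ar5")
    pv <- scenario_variant(ps, "gwp_ar5")
    alt <- total_cfp(cfp_consumption(v, cfp_production(pv)))
    pct <- round(100 * (alt - base) / base)
    expect_true(pct %in% 4:5, label = nm)
  }
})

test_that("allocation variants reorder the consumption footprint as reported", {
  cn <- scenarios_cache()[["China"]]
  nz <- paired_production("China")
  base <- total_cfp(cfp_consumption(cn, cfp_production(nz)))
  deltas <- vapply(c("fat_protein", "energy", "economic"), function(b) {
    pv <- scenario_variant(nz, paste0("allocation_", b))
    100 * (total_cfp(cfp_consumption(cn, cfp_production(pv))) - base) / base
  }, numeric(1))
  expect_lt(abs(deltas[["fat_protein"]] + 33), 3)
  expect_lt(abs(deltas[["economic"]] + 36), 3)
  # ordering matches: economic < fat_protein < energy < 0
  expect_true(deltas[["economic"]] < deltas[["fat_protein"]])
  expect_true(deltas[["fat_protein"]] < deltas[["energy"]])
  expect_lt(deltas[["energy"]], 0)
})

test_that("recipe Monte Carlo is seeded and near the baseline recipe", {
  s <- scenarios_cache()[["China"]]
  r1 <- recipe_monte_carlo(s, n = 300, seed = 5)
  r2 <- recipe_monte_carlo(s, n = 300, seed = 5)
  expect_identical(r1$draws, r2$draws)
  expect_equal(r1$baseline,
               total_cfp(cfp_consumption(s, cfp_production(
                 paired_production("China")))), tolerance = 1e-9)
  expect_lt(abs(r1$mean - r1$baseline), 1)
})
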