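# Monte Carlo propagation of parameter uncertainty through the full
# pipeline, and the recipe Monte Carlo over the feasible recipe space.
#
# Parameters are sampled independently (no correlations are specified for
# the inputs). One seed drives the whole joint draw so that results are
# bit-reproducible, and both sides of the breastfeeding comparison are
# evaluated on the same draw (the stove-efficiency draw is shared between
# the in-home BMS stages and diet cooking, which both use the same stove).

MC_PARAMETERS <- c("raw_milk_ef", "oil_ef", "electricity_use", "heat_use",
                   "sterilisation_water", "stove_efficiency", "food_ef",
                   "cooking_energy")

mc_summary_row <- function(name, draws, point = NULL) {
  m <- mean(draws)
  s <- stats::sd(draws)
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  data.frame(output = name, point = point %||% NA_real_, mean = m, sd = s,
             cv = if (m != 0) s / m else NA_real_,
             ci95_low = q[1], ci95_high = q[2], stringsAsFactors = FALSE)
}

#' Monte Carlo uncertainty propagation
#'
#' Samples the uncertain model parameters (each with its configured
#' distribution), re-evaluates the full pipeline for every draw, and
#' summarises every stage and total with mean, SD, CV and a 95% interval.
#' In `comparison` mode both CFP_Cons and CFP_BF are evaluated on the joint
#' draws and the exceedance probability `P(CFP_Cons > CFP_BF)` is reported.
#'
#' @param s a scenario (consumption scenarios are paired with
#'   `production_scenario`).
#' @param n number of draws.
#' @param seed integer seed; identical `(spec, n, seed)` give bit-identical
#'   summaries.
#' @param mode `"production"`, `"consumption"` or `"comparison"`.
#' @param production_scenario the paired production scenario (defaults to
#'   the packaged scenario named by the consumption configuration).
#' @param basis allocation basis.
#' @param gwp GWP set.
#' @param sterilisation_mode see [cfp_consumption()].
#' @param include_luc include land-use change.
#' @param param_specs named list of [dist_spec()]s per parameter; unknown
#'   names are an error before any sampling.
#' @param feeding a [feeding_parameters()] object.
#' @param keep_draws retain per-draw totals in the result?
#' @return object of class `bms_mc` with fields `n`, `seed`, `summary`
#'   (data.frame) and, for comparisons, `exceedance_probability`.
#' @export
monte_carlo <- function(s, n = 10000, seed = 1,
                        mode = c("production", "consumption", "comparison"),
                        production_scenario = NULL, basis = "dry_mass",
                        gwp = gwp_set("AR4"), sterilisation_mode = "stovetop",
                        include_luc = FALSE,
                        param_specs = mc_parameter_specs(),
                        feeding = feeding_parameters(), keep_draws = FALSE) {
  mode <- match.arg(mode)
  gwp <- as_gwp(gwp)
  unknown <- setdiff(names(param_specs), MC_PARAMETERS)
  if (length(unknown))
    stop("unknown Monte Carlo parameter: ", paste(unknown, collapse = ", "))
  set.seed(as.integer(seed))
  draw <- function(param) {
    spec <- param_specs[[param]] %||% dist_spec("point")
    sample_distribution(spec, 1, n)
  }

  prod_s <- if (mode == "production") s else {
    production_scenario %||% {
      paired <- s$consumption$production_country %||% s$country
      default_scenarios()[[paired]]
    }
  }
  if (is.null(prod_s) || is.null(prod_s$production))
    stop("no production scenario available for '", s$country, "'")

  mult <- list(raw_milk_ef = draw("raw_milk_ef"),
               oil_ef = draw("oil_ef"),
               electricity_use = draw("electricity_use"),
               heat_use = draw("heat_use"))
  prod_stages <- production_stage_values(prod_s, baseline_recipe(), basis,
                                         gwp, mult = mult)
  prod_stages <- lapply(prod_stages, rep_len, n)
  prod_total <- Reduce(`+`, prod_stages)

  summarise <- function(stage_list, point_list) {
    do.call(rbind, c(
      lapply(names(stage_list), function(nm)
        mc_summary_row(nm, stage_list[[nm]], point_list[[nm]])),
      list(mc_summary_row("total", Reduce(`+`, stage_list),
                          sum(unlist(point_list))))
    ))
  }

  out <- list(n = n, seed = seed, mode = mode, basis = basis,
              gwp = gwp$label)

  if (mode == "production") {
    point <- production_stage_values(s, baseline_recipe(), basis, gwp)
    out$summary <- summarise(prod_stages, lapply(point, `[`, 1))
    if (keep_draws) out$draws <- list(total = prod_total)
    return(structure(out, class = "bms_mc"))
  }

  mult$sterilisation_water <- draw("sterilisation_water")
  mult$stove_efficiency <- draw("stove_efficiency")
  cons_stages <- consumption_stage_values(s, prod_total, gwp,
                                          sterilisation_mode, feeding, mult)
  cons_stages <- lapply(cons_stages, rep_len, n)
  cons_total <- Reduce(`+`, cons_stages)
  point_prod <- production_stage_values(prod_s, baseline_recipe(), basis, gwp)
  point_cons <- consumption_stage_values(s, sum(vapply(point_prod, `[`,
                                                       numeric(1), 1)),
                                         gwp, sterilisation_mode, feeding)

  if (mode == "consumption") {
    out$summary <- summarise(cons_stages, lapply(point_cons, `[`, 1))
    if (keep_draws) out$draws <- list(total = cons_total)
    return(structure(out, class = "bms_mc"))
  }

  # comparison: breastfeeding side on the same joint draw
  items <- s$consumption$diet$items
  food_spec <- param_specs$food_ef %||% dist_spec("point")
  food_m <- matrix(sample_distribution(food_spec, 1, n * length(items)),
                   nrow = n)
  bf_mult <- list(food_ef = food_m,
                  cooking_energy = draw("cooking_energy"),
                  stove_efficiency = mult$stove_efficiency)
  luc_f <- s$production$luc_factors %||% prod_s$production$luc_factors %||% list()
  bf_v <- diet_cfp_values(s$consumption$diet, s$consumption$stove_profile,
                          gwp, include_luc, luc_f,
                          s$consumption$cooking_heat_mj_per_kg %||% 1.3,
                          mult = bf_mult)
  eq <- equivalent_food_energy(feeding)
  w <- as.numeric(s$consumption$bms_waste_fraction)
  bf_total_mj <- bf_v$plant + bf_v$animal + bf_v$cooking +
    if (include_luc) bf_v$luc else 0
  bf_per_kg <- rep_len(bf_total_mj * eq * (1 - w), n)

  bf_point <- cfp_breastfeeding(s, gwp, include_luc, feeding)
  diff_draws <- cons_total - bf_per_kg
  out$summary <- rbind(
    mc_summary_row("cfp_cons", cons_total,
                   sum(vapply(point_cons, `[`, numeric(1), 1))),
    mc_summary_row("cfp_bf", bf_per_kg, bf_point$per_kg_bms),
    mc_summary_row("difference", diff_draws,
                   sum(vapply(point_cons, `[`, numeric(1), 1)) -
                     bf_point$per_kg_bms)
  )
  out$exceedance_probability <- mean(diff_draws > 0)
  if (keep_draws) out$draws <- list(cons = cons_total, bf = bf_per_kg)
  structure(out, class = "bms_mc")
}

#' @export
print.bms_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo (%s), n = %d, seed = %d, basis = %s, GWP = %s\n",
              x$mode, x$n, x$seed, x$basis, x$gwp))
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$exceedance_probability))
    cat(sprintf("P(CFP_Cons > CFP_BF) = %.4f\n", x$exceedance_probability))
  invisible(x)
}

#' Recipe Monte Carlo
#'
#' Samples Codex-compliant recipes ([sample_recipes()]), evaluates the
#' consumption footprint for each recipe, and normalises every footprint to
#' the functional-unit energy density (21.7 kJ/g) by scaling with
#' `21.7 / recipe energy density`. The in-home stages are computed with the
#' recipe's own energy density (servings deliver fixed energy), which makes
#' them invariant under the normalisation.
#'
#' @param s a consumption scenario.
#' @param n number of recipes.
#' @param seed integer seed.
#' @param production_scenario paired production scenario (defaults to the
#'   packaged pairing).
#' @param gwp GWP set.
#' @param basis allocation basis.
#' @param ingredients,limits recipe configuration.
#' @param feeding a [feeding_parameters()] object.
#' @return object of class `bms_recipe_mc` with the per-recipe normalised
#'   totals (`draws`), summary statistics and the baseline-recipe value.
#' @export
recipe_monte_carlo <- function(s, n = 10000, seed = 1,
                               production_scenario = NULL,
                               gwp = gwp_set("AR4"), basis = "dry_mass",
                               ingredients = default_ingredients(),
                               limits = codex_limits(),
                               feeding = feeding_parameters()) {
  gwp <- as_gwp(gwp)
  prod_s <- production_scenario %||% {
    paired <- s$consumption$production_country %||% s$country
    default_scenarios()[[paired]]
  }
  recipes <- sample_recipes(n, seed, ingredients, limits)
  process <- process_config()
  fu_density <- feeding$bms_energy_density
  point_cons <- function(r) {
    prof <- nutrient_profile(r, ingredients)
    pr <- production_stage_values(prod_s, r, basis, gwp, process, ingredients)
    f2 <- feeding
    f2$bms_energy_density <- prof$energy_density
    # a serving delivers fixed energy, so its mass scales inversely with
    # the recipe's energy density
    f2$serving_mass <- feeding$serving_mass * fu_density / prof$energy_density
    cs <- consumption_stage_values(s, sum(vapply(pr, `[`, numeric(1), 1)),
                                   gwp, "stovetop", f2)
    sum(vapply(cs, `[`, numeric(1), 1)) * fu_density / prof$energy_density
  }
  draws <- vapply(recipes, point_cons, numeric(1))
  baseline <- point_cons(baseline_recipe())
  structure(list(n = n, seed = seed, draws = draws,
                 mean = mean(draws), sd = stats::sd(draws),
                 cv = stats::sd(draws) / mean(draws),
                 ci95 = stats::quantile(draws, c(0.025, 0.975), names = FALSE),
                 baseline = baseline,
                 acceptance_rate = attr(recipes, "acceptance_rate")),
            class = "bms_recipe_mc")
}

#' @export
print.bms_recipe_mc <- function(x, ...) {
  cat(sprintf("Recipe Monte Carlo, n = %d: mean %.2f (CV %.1f%%), baseline %.2f\n",
              x$n, x$mean, 100 * x$cv, x$baseline))
  cat(sprintf("95%% of recipes in [%.2f, %.2f] kg CO2e/kg BMS\n",
              x$ci95[1], x$ci95[2]))
  invisible(x)
}
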