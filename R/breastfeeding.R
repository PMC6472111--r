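# Breastfeeding equivalence: the footprint of producing, distributing and
# cooking the additional maternal food that replaces 1 kg of BMS powder
# (CFP_BF), and the comparison with CFP_Cons.

#' Food energy equivalent to 1 kg of BMS
#'
#' Breastfeeding mothers need additional food energy over the six-month
#' period; dividing the period's additional food energy by the BMS mass fed
#' over the same period gives the MJ of food equivalent to 1 kg of powder
#' (385 MJ / 21 kg, about 18 MJ). The unrounded value is used internally;
#' table output rounds to the nearest MJ.
#'
#' @param p a [feeding_parameters()] object.
#' @return MJ food per kg BMS (unrounded).
#' @export
equivalent_food_energy <- function(p = feeding_parameters()) {
  if (p$period_bms_mass <= 0) stop("period BMS mass must be positive")
  p$period_total_food / p$period_bms_mass
}

# Internal vectorised diet computation. mult$food_ef may be a draws x items
# matrix; mult$cooking_energy and mult$stove_efficiency vectors of draws.
diet_cfp_values <- function(diet, stove_profile, gwp = gwp_set("AR4"),
                            include_luc = FALSE, luc_factors = list(),
                            cooking_heat_mj_per_kg = 1.3, mult = list()) {
  items <- diet$items
  n_items <- length(items)
  food_m <- mult$food_ef %||% matrix(1, nrow = 1, ncol = n_items)
  if (!is.matrix(food_m)) food_m <- matrix(food_m, ncol = n_items)
  m_cook <- mult$cooking_energy %||% 1
  m_eff <- mult$stove_efficiency %||% 1

  prod_terms <- vapply(items, function(it)
    it$share * ef_value(it$ef_per_mj, gwp) / (1 - it$household_waste),
    numeric(1))
  cat_plant <- vapply(items, function(it) it$category == "plant", logical(1))
  plant <- as.vector(food_m[, cat_plant, drop = FALSE] %*%
                       prod_terms[cat_plant])
  animal <- as.vector(food_m[, !cat_plant, drop = FALSE] %*%
                        prod_terms[!cat_plant])

  mass_int <- sum(vapply(items, function(it) it$share * it$mass_per_mj,
                         numeric(1)))
  ef_del <- stove_delivered_ef(stove_profile, gwp, m_eff)
  cooking <- mass_int * cooking_heat_mj_per_kg * m_cook * ef_del

  luc <- 0
  if (include_luc) {
    luc <- sum(vapply(items, function(it) {
      com <- it$luc_commodity
      if (is.null(com) || is.na(com) || !nzchar(com)) return(0)
      it$share * it$mass_per_mj * (luc_factors[[com]] %||% 0)
    }, numeric(1)))
  }
  list(plant = plant, animal = animal, cooking = cooking, luc = luc)
}

#' Footprint of an average diet per MJ consumed
#'
#' Production-and-distribution term per MJ consumed (emission factors
#' inflated by household waste), a cooking term (1.3 MJ of delivered heat
#' per kg of food, through the country stove profile), and an optional
#' land-use-change add-on over the LUC-associated commodities.
#'
#' @param diet diet specification (list with `items`).
#' @param stove_profile stove profile, as in [home_energy_cfp()].
#' @param gwp GWP set.
#' @param include_luc include the LUC add-on?
#' @param luc_factors named kg CO2e per kg commodity.
#' @param cooking_heat_mj_per_kg delivered cooking heat per kg food.
#' @return object of class `bms_bf` with per-MJ fields `plant`, `animal`,
#'   `cooking`, `total` and `luc`.
#' @export
diet_cfp <- function(diet, stove_profile, gwp = gwp_set("AR4"),
                     include_luc = FALSE, luc_factors = list(),
                     cooking_heat_mj_per_kg = 1.3) {
  v <- diet_cfp_values(diet, stove_profile, as_gwp(gwp), include_luc,
                       luc_factors, cooking_heat_mj_per_kg)
  structure(list(plant = v$plant[1], animal = v$animal[1],
                 cooking = v$cooking[1],
                 total = v$plant[1] + v$animal[1] + v$cooking[1],
                 luc = v$luc[1]),
            class = "bms_bf")
}

#' @export
print.bms_bf <- function(x, ...) {
  cat(sprintf("plant %.3f + animal %.3f + cooking %.3f = %.3f kg CO2e/MJ\n",
              x$plant, x$animal, x$cooking, x$total))
  if (!is.null(x$per_kg_bms))
    cat(sprintf("per kg BMS equivalent: %.2f kg CO2e\n", x$per_kg_bms))
  invisible(x)
}

#' Breastfeeding footprint per kg of BMS (CFP_BF)
#'
#' The diet footprint per MJ times the equivalent food energy, reduced by
#' the consumer-stage BMS waste fraction (wasted BMS needs no breastmilk to
#' replace it).
#'
#' @param s a consumption (or `both`) scenario.
#' @param gwp GWP set; defaults to the scenario's `gwp` or AR4.
#' @param include_luc include the land-use-change add-on?
#' @param feeding a [feeding_parameters()] object.
#' @param bms_waste_fraction override of the scenario's BMS waste fraction.
#' @return a `bms_bf` object with the per-MJ fields plus `per_kg_bms` and
#'   `luc_addon` (kg CO2e per kg BMS).
#' @export
cfp_breastfeeding <- function(s, gwp = NULL, include_luc = FALSE,
                              feeding = feeding_parameters(),
                              bms_waste_fraction = NULL) {
  cns <- s$consumption
  if (is.null(cns)) stop("scenario '", s$country, "' has no consumption role")
  gwp <- as_gwp(gwp %||% s$gwp %||% "AR4")
  luc_f <- s$production$luc_factors %||% list()
  res <- diet_cfp(cns$diet, cns$stove_profile, gwp, include_luc, luc_f,
                  cns$cooking_heat_mj_per_kg %||% 1.3)
  w <- bms_waste_fraction %||% as.numeric(cns$bms_waste_fraction)
  eq <- equivalent_food_energy(feeding)
  res$per_kg_bms <- (res$total + if (include_luc) res$luc else 0) *
    eq * (1 - w)
  res$luc_addon <- res$luc * eq * (1 - w)
  attr(res, "gwp") <- gwp$label
  attr(res, "scenario") <- s$country
  res
}

#' Compare consumption and breastfeeding footprints
#'
#' @param cons a [cfp_consumption()] result.
#' @param bf a [cfp_breastfeeding()] result for the same scenario and GWP
#'   set.
#' @return list of class `bms_comparison` with `difference`
#'   (CFP_Cons - CFP_BF, positive when feeding BMS has the higher
#'   footprint), `ratio` (CFP_BF / CFP_Cons) and `exceedance_probability`
#'   (`NA` until filled by [monte_carlo()]).
#' @export
compare_footprints <- function(cons, bf) {
  g1 <- attr(cons, "gwp"); g2 <- attr(bf, "gwp")
  if (!is.null(g1) && !is.null(g2) && !identical(g1, g2))
    stop("mismatched GWP sets: ", g1, " vs ", g2)
  cons_total <- total_cfp(cons)
  structure(list(cfp_cons = cons_total, cfp_bf = bf$per_kg_bms,
                 difference = cons_total - bf$per_kg_bms,
                 ratio = bf$per_kg_bms / cons_total,
                 exceedance_probability = NA_real_),
            class = "bms_comparison")
}

#' @export
print.bms_comparison <- function(x, ...) {
  cat(sprintf("CFP_Cons %.2f vs CFP_BF %.2f kg CO2e/kg BMS\n",
              x$cfp_cons, x$cfp_bf))
  cat(sprintf("difference %.2f (ratio BF/Cons %.2f)\n", x$difference, x$ratio))
  if (!is.na(x$exceedance_probability))
    cat(sprintf("P(CFP_Cons > CFP_BF) = %.3f\n", x$exceedance_probability))
  invisible(x)
}

#' Sweep the comparison over BMS waste levels
#'
#' Evaluates CFP_Cons (independent of consumer-stage BMS waste) and CFP_BF
#' (decreasing in it) over a grid of waste fractions.
#'
#' @param s a consumption scenario.
#' @param production_result paired [cfp_production()] result.
#' @param waste_grid numeric grid of waste fractions in `[0, 1)`.
#' @param gwp GWP set.
#' @param sterilisation_mode see [cfp_consumption()].
#' @param feeding a [feeding_parameters()] object.
#' @return data.frame with columns `waste`, `cfp_cons`, `cfp_bf`,
#'   `difference`, `ratio`.
#' @export
waste_sweep <- function(s, production_result,
                        waste_grid = seq(0, 0.5, by = 0.05), gwp = NULL,
                        sterilisation_mode = NULL,
                        feeding = feeding_parameters()) {
  cons <- cfp_consumption(s, production_result, gwp, sterilisation_mode,
                          feeding)
  rows <- lapply(waste_grid, function(w) {
    bf <- cfp_breastfeeding(s, gwp, feeding = feeding,
                            bms_waste_fraction = w)
    data.frame(waste = w, cfp_cons = total_cfp(cons), cfp_bf = bf$per_kg_bms,
               difference = total_cfp(cons) - bf$per_kg_bms,
               ratio = bf$per_kg_bms / total_cfp(cons))
  })
  do.call(rbind, rows)
}
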