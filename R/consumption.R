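# Cradle-to-bottle consumption footprint (CFP_Cons): production, transport
# to retail, bottle manufacture, and in-home sterilisation and preparation.

#' Feeding plan per kg of BMS powder
#'
#' Derived quantities of the feeding model: servings per kg (1000 g divided
#' by the serving mass, rounded to the nearest bottle), sterilisation
#' batches, water heated for preparation and sterilisation, and amortised
#' bottle manufacture.
#'
#' @param p a [feeding_parameters()] object.
#' @return list of class `bms_feeding_plan`.
#' @export
feeding_plan <- function(p = feeding_parameters()) {
  if (p$serving_mass <= 0) stop("serving mass must be positive")
  servings <- round(1000 / p$serving_mass)
  batches <- servings / p$bottles_per_batch
  structure(list(
    servings_per_kg = servings,
    bottles_to_sterilise_per_kg = servings,
    sterilisation_batches_per_kg = batches,
    water_heated_for_prep = servings * p$water_per_bottle,
    water_heated_for_sterilisation = batches * p$sterilisation_water,
    bottles_manufactured_per_kg = p$bottles_per_period / p$period_bms_mass
  ), class = "bms_feeding_plan")
}

# delivered-heat emission factor of a stove profile, kg CO2e per MJ of heat
# delivered to the pot: sum of share * fuel EF / efficiency
stove_delivered_ef <- function(stove_profile, gwp = gwp_set("AR4"),
                               efficiency_multiplier = 1) {
  shares <- vapply(stove_profile, `[[`, numeric(1), "share")
  if (!is_mixture(shares)) stop("stove shares must sum to 1")
  out <- 0
  for (f in stove_profile) {
    if (any(f$efficiency * efficiency_multiplier <= 0))
      stop("stove efficiency must be positive")
    out <- out + f$share * ef_value(f$ef, gwp) /
      (f$efficiency * efficiency_multiplier)
  }
  out
}

# MJ needed to bring 1 L of water from ambient to the boil
heat_per_litre <- function(ambient_temp_c = 20) {
  4.186 * (100 - ambient_temp_c) / 1000
}

#' In-home sterilisation and preparation footprint
#'
#' Heat demand is the water volume times the specific heat times the
#' temperature rise to the boil; sterilisation is additionally scaled by a
#' per-batch boil-duration factor (heat to keep the batch boiling,
#' calibrated). Delivered heat is converted to fuel through the stove
#' efficiencies and fuel emission factors.
#'
#' @param plan a [feeding_plan()].
#' @param stove_profile named list of fuels with `share`, `ef`, `efficiency`.
#' @param gwp GWP set.
#' @param boil_factor per-batch sterilisation boil-duration factor.
#' @param ambient_temp_c ambient water temperature (degrees C).
#' @param mult optional Monte Carlo multipliers (`sterilisation_water`,
#'   `stove_efficiency`).
#' @return named vector/list with `sterilisation` and `preparation`
#'   (kg CO2e per kg BMS).
#' @export
home_energy_cfp <- function(plan, stove_profile, gwp = gwp_set("AR4"),
                            boil_factor = 1, ambient_temp_c = 20,
                            mult = list()) {
  m_w <- mult$sterilisation_water %||% 1
  m_e <- mult$stove_efficiency %||% 1
  hpl <- heat_per_litre(ambient_temp_c)
  ef_del <- stove_delivered_ef(stove_profile, gwp, m_e)
  list(sterilisation = plan$water_heated_for_sterilisation * m_w * hpl *
         boil_factor * ef_del,
       preparation = plan$water_heated_for_prep * hpl * ef_del)
}

# Internal vectorised consumption stages
consumption_stage_values <- function(s, production_total, gwp = gwp_set("AR4"),
                                     sterilisation_mode = "stovetop",
                                     feeding = feeding_parameters(),
                                     mult = list()) {
  cns <- s$consumption
  if (is.null(cns)) stop("scenario '", s$country, "' has no consumption role")
  if (is.null(production_total))
    stop("missing paired production result for '", s$country, "'")
  sterilisation_mode <- match.arg(sterilisation_mode,
                                  c("stovetop", "steam", "none"))
  plan <- feeding_plan(feeding)
  home <- home_energy_cfp(plan, cns$stove_profile, gwp,
                          boil_factor = cns$sterilisation_boil_factor %||% 1,
                          ambient_temp_c = cns$ambient_temp_c %||% 20,
                          mult = mult)
  ster <- switch(sterilisation_mode,
                 stovetop = home$sterilisation,
                 steam = home$sterilisation * (cns$steam_steriliser_factor %||% 0.14),
                 none = home$sterilisation * 0)
  transport <- 0
  for (leg in cns$retail_transport_legs) {
    transport <- transport + (leg$mass_kg %||% 1) * leg$distance_km *
      leg$ef / 1000
  }
  bottle <- plan$bottles_manufactured_per_kg * cns$bottle$mass_kg *
    cns$bottle$ef
  list(bms_production = production_total,
       sterilisation = ster,
       preparation = home$preparation,
       transport = transport,
       bottle_production = bottle)
}

#' Cradle-to-bottle consumption footprint (CFP_Cons)
#'
#' The consumption footprint of 1 kg of BMS powder: the production
#' footprint of the paired production country, transport from plant to
#' retail, baby-bottle manufacture, and in-home bottle sterilisation and
#' BMS preparation.
#'
#' @param s a consumption (or `both`) scenario.
#' @param production_result a [cfp_production()] result for the paired
#'   production country (or a numeric total).
#' @param gwp GWP set; defaults to the scenario's `gwp` or AR4.
#' @param sterilisation_mode `"stovetop"` (boiling, the default), `"steam"`
#'   (electric steam steriliser, scaled by the configured factor) or
#'   `"none"`.
#' @param feeding a [feeding_parameters()] object.
#' @return a [stage_breakdown()] with stages `bms_production`,
#'   `sterilisation`, `preparation`, `transport`, `bottle_production`.
#' @export
cfp_consumption <- function(s, production_result, gwp = NULL,
                            sterilisation_mode = NULL,
                            feeding = feeding_parameters()) {
  if (is.null(production_result) || (is.numeric(production_result) &&
                                     !length(production_result)))
    stop("missing paired production result for '", s$country, "'")
  gwp <- as_gwp(gwp %||% s$gwp %||% "AR4")
  sterilisation_mode <- sterilisation_mode %||% s$sterilisation_mode %||% "stovetop"
  prod_gwp <- if (inherits(production_result, "bms_stages"))
    attr(production_result, "gwp") else NULL
  if (!is.null(prod_gwp) && !identical(prod_gwp, gwp$label))
    stop("production result uses GWP set ", prod_gwp,
         " but consumption requested ", gwp$label)
  total <- if (inherits(production_result, "bms_stages"))
    total_cfp(production_result) else as.numeric(production_result)
  st <- consumption_stage_values(s, total, gwp, sterilisation_mode,
                                 feeding = feeding)
  stage_breakdown(vapply(st, function(x) x[1], numeric(1)),
                  scenario = s$country, gwp = gwp$label,
                  sterilisation_mode = sterilisation_mode,
                  basis = if (inherits(production_result, "bms_stages"))
                    attr(production_result, "basis") else NULL)
}
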