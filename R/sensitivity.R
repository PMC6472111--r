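# One-at-a-time sensitivity analysis and scenario switches.

deep_copy <- function(x) x  # R copy-on-modify; named for intent

oat_mutators <- list(
  raw_milk_ef = function(s, f, ctx) {
    s$production$raw_milk_ef$value <- s$production$raw_milk_ef$value * f
    list(s = s, ctx = ctx)
  },
  oil_ef = function(s, f, ctx) {
    s$production$oil_efs <- lapply(s$production$oil_efs, function(ef) {
      ef$value <- ef$value * f; ef
    })
    list(s = s, ctx = ctx)
  },
  electricity_use = function(s, f, ctx) {
    ctx$mult$electricity_use <- f; list(s = s, ctx = ctx)
  },
  heat_use = function(s, f, ctx) {
    ctx$mult$heat_use <- f; list(s = s, ctx = ctx)
  },
  electricity_ef = function(s, f, ctx) {
    s$production$electricity_ef$value <- s$production$electricity_ef$value * f
    list(s = s, ctx = ctx)
  },
  heat_ef = function(s, f, ctx) {
    s$production$heat_ef$value <- s$production$heat_ef$value * f
    list(s = s, ctx = ctx)
  },
  transport_distance = function(s, f, ctx) {
    s$production$transport_legs <- lapply(s$production$transport_legs,
                                          function(l) {
                                            l$distance_km <- l$distance_km * f; l
                                          })
    s$production$oil_sea_distance_km <- s$production$oil_sea_distance_km * f
    if (!is.null(s$consumption))
      s$consumption$retail_transport_legs <-
        lapply(s$consumption$retail_transport_legs, function(l) {
          l$distance_km <- l$distance_km * f; l
        })
    list(s = s, ctx = ctx)
  },
  packaging_ef = function(s, f, ctx) {
    s$production$packaging_efs <- lapply(s$production$packaging_efs,
                                         function(ef) {
                                           ef$value <- ef$value * f; ef
                                         })
    list(s = s, ctx = ctx)
  },
  chain_waste = function(s, f, ctx) {
    s$production$chain_waste <- pmin(s$production$chain_waste * f, 0.999)
    list(s = s, ctx = ctx)
  },
  stove_fuel_efs = function(s, f, ctx) {
    s$consumption$stove_profile <- lapply(s$consumption$stove_profile,
                                          function(fl) {
                                            fl$ef$value <- fl$ef$value * f; fl
                                          })
    list(s = s, ctx = ctx)
  },
  stove_efficiency = function(s, f, ctx) {
    ctx$mult$stove_efficiency <- f; list(s = s, ctx = ctx)
  },
  sterilisation_water = function(s, f, ctx) {
    ctx$mult$sterilisation_water <- f; list(s = s, ctx = ctx)
  },
  serving_mass = function(s, f, ctx) {
    ctx$feeding$serving_mass <- ctx$feeding$serving_mass * f
    list(s = s, ctx = ctx)
  },
  retail_distance = function(s, f, ctx) {
    if (!is.null(s$consumption))
      s$consumption$retail_transport_legs <-
        lapply(s$consumption$retail_transport_legs, function(l) {
          l$distance_km <- l$distance_km * f; l
        })
    list(s = s, ctx = ctx)
  }
)

OAT_PRODUCTION_PARAMETERS <- c("raw_milk_ef", "oil_ef", "electricity_use",
                               "heat_use", "electricity_ef", "heat_ef",
                               "transport_distance", "packaging_ef",
                               "chain_waste")
OAT_CONSUMPTION_PARAMETERS <- c("stove_fuel_efs", "stove_efficiency",
                                "sterilisation_water", "serving_mass",
                                "retail_distance", "transport_distance")

oat_total <- function(s, ctx, target, production_scenario, basis, gwp) {
  if (target == "production") {
    st <- production_stage_values(s, baseline_recipe(), basis, gwp,
                                  mult = ctx$mult)
    return(sum(vapply(st, `[`, numeric(1), 1)))
  }
  ps <- production_scenario
  pst <- production_stage_values(ps, baseline_recipe(), basis, gwp,
                                 mult = ctx$mult)
  cst <- consumption_stage_values(s, sum(vapply(pst, `[`, numeric(1), 1)),
                                  gwp, "stovetop", ctx$feeding, ctx$mult)
  sum(vapply(cst, `[`, numeric(1), 1))
}

#' One-at-a-time sensitivity analysis
#'
#' Perturbs each parameter by `+/- perturbation` (default 10%), re-evaluates
#' the pipeline, and reports the signed percent change of the target total.
#' Parameters the model does not use report 0%.
#'
#' @param s the scenario to analyse.
#' @param parameters parameter names; defaults to the full set for the
#'   target.
#' @param perturbation relative perturbation (> 0).
#' @param target `"production"` (CFP_Prod of `s`) or `"consumption"`
#'   (CFP_Cons of `s` with its paired production country).
#' @param production_scenario paired production scenario for consumption
#'   targets.
#' @param basis allocation basis.
#' @param gwp GWP set.
#' @return data.frame with columns `parameter`, `pct_change_low` (at
#'   `1 - perturbation`) and `pct_change_high` (at `1 + perturbation`).
#' @export
oat_sensitivity <- function(s, parameters = NULL, perturbation = 0.1,
                            target = c("production", "consumption"),
                            production_scenario = NULL, basis = "dry_mass",
                            gwp = gwp_set("AR4")) {
  stopifnot(perturbation > 0)
  target <- match.arg(target)
  gwp <- as_gwp(gwp)
  parameters <- parameters %||% switch(target,
                                       production = OAT_PRODUCTION_PARAMETERS,
                                       consumption = OAT_CONSUMPTION_PARAMETERS)
  unknown <- setdiff(parameters, names(oat_mutators))
  if (length(unknown)) stop("unknown OAT parameter: ",
                            paste(unknown, collapse = ", "))
  if (target == "consumption") {
    production_scenario <- production_scenario %||% {
      paired <- s$consumption$production_country %||% s$country
      default_scenarios()[[paired]]
    }
  }
  base_ctx <- list(mult = list(), feeding = feeding_parameters())
  base <- oat_total(s, base_ctx, target, production_scenario, basis, gwp)
  rows <- lapply(parameters, function(par) {
    evald <- vapply(c(1 - perturbation, 1 + perturbation), function(f) {
      mut <- oat_mutators[[par]](deep_copy(s), f, base_ctx)
      oat_total(mut$s, mut$ctx, target, production_scenario, basis, gwp)
    }, numeric(1))
    data.frame(parameter = par,
               pct_change_low = 100 * (evald[1] - base) / base,
               pct_change_high = 100 * (evald[2] - base) / base,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_total") <- base
  attr(out, "target") <- target
  out
}

SCENARIO_SWITCHES <- c("identity", "packaging_tin_can", "packaging_bag_in_box",
                       "sterilisation_steam", "sterilisation_none",
                       "allocation_dry_mass", "allocation_fat_protein",
                       "allocation_energy", "allocation_economic",
                       "gwp_ar5", "gwp_ar5_feedback", "include_luc",
                       "vitamins")

#' Scenario variant switches
#'
#' Returns a modified copy of a scenario implementing one of the sensitivity
#' switches: packaging entirely in tin cans or bag-in-boxes, steam or no
#' sterilisation, an alternative allocation basis, an alternative GWP set,
#' inclusion of land-use change, or the micronutrient (vitamin and mineral)
#' add-on (2% of powder mass times an additive emission factor). The
#' pipeline functions read the switch fields from the scenario, so the
#' variant scenario can be passed anywhere the original could.
#'
#' @param s a scenario.
#' @param switch one of `identity`, `packaging_tin_can`,
#'   `packaging_bag_in_box`, `sterilisation_steam`, `sterilisation_none`,
#'   `allocation_dry_mass`, `allocation_fat_protein`, `allocation_energy`,
#'   `allocation_economic`, `gwp_ar5`, `gwp_ar5_feedback`, `include_luc`,
#'   `vitamins`.
#' @param vitamin_ef additive emission factor (kg CO2e per kg additive) for
#'   the `vitamins` switch; defaults to the highest packaged additive EF.
#' @return modified scenario (the `identity` switch returns an equal
#'   scenario).
#' @export
scenario_variant <- function(s, switch = "identity", vitamin_ef = NULL) {
  if (!switch %in% SCENARIO_SWITCHES)
    stop("unknown scenario switch: ", switch)
  v <- deep_copy(s)
  if (switch == "identity") return(v)
  if (switch == "packaging_tin_can" || switch == "packaging_bag_in_box") {
    tin <- as.numeric(switch == "packaging_tin_can")
    v$production$packaging_mix <- list(tin_can = tin, bag_in_box = 1 - tin)
    return(v)
  }
  if (switch == "sterilisation_steam") { v$sterilisation_mode <- "steam"; return(v) }
  if (switch == "sterilisation_none") { v$sterilisation_mode <- "none"; return(v) }
  if (startsWith(switch, "allocation_")) {
    v$allocation_basis <- sub("^allocation_", "", switch)
    return(v)
  }
  if (switch == "gwp_ar5") { v$gwp <- "AR5"; return(v) }
  if (switch == "gwp_ar5_feedback") { v$gwp <- "AR5-feedback"; return(v) }
  if (switch == "include_luc") {
    if (!is.null(v$production)) v$production$include_luc <- TRUE
    v$include_luc <- TRUE
    return(v)
  }
  # vitamins
  vit <- vitamin_config()
  ef <- vitamin_ef %||% max(unlist(vit$additive_efs))
  v$production$vitamin_addon <- list(mass_fraction = vit$mass_fraction,
                                     ef = ef)
  v
}
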