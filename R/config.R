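# Configuration loading. All scenario parameters live in YAML documents
# under inst/extdata/config: one file per country plus shared files for the
# process chain, the feeding plan, the recipe ingredient table and the
# micronutrient add-on. Values calibrated against the printed result tables
# (rather than printed inputs) carry `calibrated: true` in the configs.

config_dir <- function(dir = NULL) {
  dir %||% system.file("extdata", "config", package = "bmslca")
}

read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("missing configuration file: ", path)
  yaml::read_yaml(path)
}

#' Shared process-chain configuration
#'
#' Milk and whey compositions, step energy intensities, co-product prices and
#' energy coefficients used by [dairy_mass_balance()]. The milk composition
#' is an effective, calibrated composition: it is chosen so that the default
#' recipe's mass balance reproduces the reference raw-milk input and
#' dry-mass-allocated quantity, not a farm-gate milk assay.
#'
#' @param dir optional alternative configuration directory.
#' @return nested list.
#' @export
process_config <- function(dir = NULL) {
  cfg <- read_config_yaml(file.path(config_dir(dir), "shared", "process.yaml"))
  cfg
}

#' Feeding parameters
#'
#' The feeding-plan defaults: average infant intake 2480 kJ/day over six
#' feeds (18.6 g powder and 0.13 L water per serving), sterilisation of six
#' bottles per batch in 5 L of boiled water, six bottles used over the
#' 184-day period, 21 kg powder fed over the period, and the breastfeeding
#' side's 500 kcal/day of additional maternal food (385 MJ over the period).
#'
#' @param ... overrides for individual fields.
#' @param dir optional alternative configuration directory.
#' @return list of class `bms_feeding`.
#' @export
feeding_parameters <- function(..., dir = NULL) {
  cfg <- read_config_yaml(file.path(config_dir(dir), "shared", "feeding.yaml"))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown feeding parameter: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  vals <- unlist(cfg)
  if (any(vals <= 0)) stop("feeding parameters must be strictly positive")
  per_serving <- cfg$infant_energy_per_day / cfg$feeds_per_day
  implied <- cfg$serving_mass * cfg$bms_energy_density
  if (abs(implied - per_serving) / per_serving > 0.03)
    stop("serving mass x energy density inconsistent with per-serving energy")
  structure(cfg, class = "bms_feeding")
}

#' Micronutrient add-on configuration
#'
#' Vitamins and minerals make up about 2% of the powder and are excluded
#' from the recipe mass balance; their footprint is assessed as a scenario
#' add-on using the span of published additive emission factors.
#'
#' @param dir optional alternative configuration directory.
#' @return list with `mass_fraction` and named `additive_efs`.
#' @export
vitamin_config <- function(dir = NULL) {
  read_config_yaml(file.path(config_dir(dir), "shared", "vitamins.yaml"))
}

#' Monte Carlo parameter uncertainty grammar
#'
#' The packaged uncertainty set: the distribution attached to each sampled
#' model parameter.
#'
#' @param dir optional alternative configuration directory.
#' @return named list of [dist_spec()]s.
#' @export
mc_parameter_specs <- function(dir = NULL) {
  raw <- read_config_yaml(file.path(config_dir(dir), "shared",
                                    "distributions.yaml"))
  lapply(raw, as_dist_spec)
}

# normalise a YAML emission-factor entry into a bms_ef
parse_ef <- function(entry, unit = "kg CO2e per unit") {
  if (is.numeric(entry)) return(emission_factor(entry, unit))
  emission_factor(value = entry$value,
                  unit = entry$unit %||% unit,
                  gas_shares = entry$gas_shares %||% c(co2 = 1, ch4 = 0, n2o = 0),
                  distribution = if (is.null(entry$distribution)) NULL else
                    as_dist_spec(entry$distribution),
                  calibrated = entry$calibrated %||% FALSE)
}

parse_production <- function(p) {
  p$raw_milk_ef <- parse_ef(p$raw_milk_ef, "kg CO2e per kg ECM")
  p$electricity_ef <- parse_ef(p$electricity_ef, "kg CO2e per MJ electricity")
  p$heat_ef <- parse_ef(p$heat_ef, "kg CO2e per MJ heat")
  p$oil_efs <- lapply(p$oil_efs, parse_ef, unit = "kg CO2e per kg oil")
  p$packaging_efs <- lapply(p$packaging_efs, parse_ef,
                            unit = "kg CO2e per kg packaging material")
  p$sea_transport_ef <- parse_ef(p$sea_transport_ef, "kg CO2e per tonne km")
  p$chain_waste <- as.numeric(unlist(p$chain_waste %||% numeric()))
  p
}

parse_consumption <- function(cns) {
  cns$stove_profile <- lapply(cns$stove_profile, function(f) {
    f$ef <- parse_ef(f$ef, "kg CO2e per MJ fuel")
    f
  })
  cns$diet$items <- lapply(cns$diet$items, function(it) {
    it$ef_per_mj <- parse_ef(it$ef_per_mj, "kg CO2e per MJ food")
    it
  })
  w <- cns$bms_waste_fraction
  if (is.list(w)) {
    cns$bms_waste_fraction <- w$value
    attr(cns$bms_waste_fraction, "calibrated") <- isTRUE(w$calibrated)
  }
  cns
}

load_scenario_file <- function(path) {
  raw <- read_config_yaml(path)
  s <- list(country = raw$country, role = raw$role)
  if (!is.null(raw$production)) s$production <- parse_production(raw$production)
  if (!is.null(raw$consumption)) s$consumption <- parse_consumption(raw$consumption)
  s <- structure(s, class = "bms_scenario")
  rep <- validate_scenario(s)
  if (nrow(rep) > 0)
    stop("malformed scenario configuration '", basename(path), "': ",
         paste(paste0(rep$field, " (", rep$message, ")"), collapse = "; "))
  s
}

#' Packaged default country scenarios
#'
#' Loads the packaged scenarios: four production countries (New Zealand,
#' United States, Brazil, France) and four consumption countries (United
#' Kingdom, China, Brazil, Vietnam). Brazil produces and consumes its own
#' BMS and is returned once with role `both`; the other consumption
#' countries name their paired production country (UK and Vietnam are
#' supplied from France, China from New Zealand).
#'
#' @param dir optional alternative configuration directory.
#' @return named list of `bms_scenario` objects.
#' @export
default_scenarios <- function(dir = NULL) {
  files <- list.files(file.path(config_dir(dir), "countries"),
                      pattern = "\\.yaml$", full.names = TRUE)
  if (!length(files)) stop("no packaged scenario configurations found")
  scens <- lapply(files, load_scenario_file)
  names(scens) <- vapply(scens, `[[`, character(1), "country")
  order <- c("New Zealand", "United States", "Brazil", "France",
             "United Kingdom", "China", "Vietnam")
  scens[intersect(order, names(scens))]
}

#' @export
print.bms_scenario <- function(x, ...) {
  cat("<bms_scenario>", x$country, "- role:", x$role, "\n")
  if (!is.null(x$production))
    cat("  raw milk EF:", x$production$raw_milk_ef$value, "kg CO2e/kg ECM\n")
  if (!is.null(x$consumption))
    cat("  paired production country:",
        x$consumption$production_country %||% x$country, "\n")
  invisible(x)
}
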