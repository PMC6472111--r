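# Scenario validation, serialisation round-trip, and the synthetic-scenario
# generator used for property testing.

add_issue <- function(issues, field, message) {
  rbind(issues, data.frame(field = field, message = message,
                           stringsAsFactors = FALSE))
}

check_mixture <- function(issues, x, field) {
  v <- unlist(x)
  if (any(v < -1e-9) || any(v > 1 + 1e-9))
    issues <- add_issue(issues, field, "shares must lie in [0, 1]")
  if (abs(sum(v) - 1) > 1e-9)
    issues <- add_issue(issues, field,
                        sprintf("shares sum to %.6f, expected 1", sum(v)))
  issues
}

check_ef <- function(issues, ef, field) {
  if (!inherits(ef, "bms_ef")) {
    return(add_issue(issues, field, "not an emission factor"))
  }
  if (ef$value < 0) issues <- add_issue(issues, field, "value must be >= 0")
  issues <- check_mixture(issues, ef$gas_shares, paste0(field, ".gas_shares"))
  issues
}

#' Validate a country scenario
#'
#' Checks every scenario invariant (mixtures summing to one, waste fractions
#' in `[0, 1)`, non-negative emission factors and distances, milk/meat
#' allocation in `(0, 1]`) and reports each violation with its field path.
#'
#' @param s a `bms_scenario`.
#' @return data.frame with columns `field` and `message`; zero rows when the
#'   scenario is valid.
#' @export
validate_scenario <- function(s) {
  issues <- data.frame(field = character(), message = character(),
                       stringsAsFactors = FALSE)
  if (is.null(s$country) || !nzchar(s$country))
    issues <- add_issue(issues, "country", "missing country name")
  if (!isTRUE(s$role %in% c("production", "consumption", "both")))
    issues <- add_issue(issues, "role",
                        "role must be production, consumption or both")
  p <- s$production
  if (!is.null(p)) {
    issues <- check_ef(issues, p$raw_milk_ef, "production.raw_milk_ef")
    issues <- check_ef(issues, p$electricity_ef, "production.electricity_ef")
    issues <- check_ef(issues, p$heat_ef, "production.heat_ef")
    if (!is.null(p$milk_density) && p$milk_density <= 0)
      issues <- add_issue(issues, "production.milk_density", "must be > 0")
    mm <- p$milk_meat_allocation
    if (is.null(mm) || mm <= 0 || mm > 1)
      issues <- add_issue(issues, "production.milk_meat_allocation",
                          "must lie in (0, 1]")
    issues <- check_mixture(issues, p$oil_blend, "production.oil_blend")
    if (!all(names(p$oil_blend) %in% names(p$oil_efs)))
      issues <- add_issue(issues, "production.oil_efs",
                          "missing emission factor for an oil in the blend")
    for (nm in names(p$oil_efs))
      issues <- check_ef(issues, p$oil_efs[[nm]],
                         paste0("production.oil_efs.", nm))
    issues <- check_mixture(issues, p$packaging_mix, "production.packaging_mix")
    for (nm in names(p$packaging_efs))
      issues <- check_ef(issues, p$packaging_efs[[nm]],
                         paste0("production.packaging_efs.", nm))
    cw <- p$chain_waste
    if (length(cw) && (any(cw < 0) || any(cw >= 1)))
      issues <- add_issue(issues, "production.chain_waste",
                          "waste fractions must lie in [0, 1)")
    for (i in seq_along(p$transport_legs)) {
      leg <- p$transport_legs[[i]]
      if ((leg$distance_km %||% 0) < 0)
        issues <- add_issue(issues,
                            sprintf("production.transport_legs[%d].distance_km", i),
                            "distance must be >= 0")
      if ((leg$ef %||% 0) < 0)
        issues <- add_issue(issues,
                            sprintf("production.transport_legs[%d].ef", i),
                            "emission factor must be >= 0")
    }
    if ((p$oil_sea_distance_km %||% 0) < 0)
      issues <- add_issue(issues, "production.oil_sea_distance_km",
                          "distance must be >= 0")
    if (!is.null(p$luc_factors) && any(unlist(p$luc_factors) < 0))
      issues <- add_issue(issues, "production.luc_factors", "must be >= 0")
  }
  cns <- s$consumption
  if (!is.null(cns)) {
    shares <- vapply(cns$stove_profile, `[[`, numeric(1), "share")
    issues <- check_mixture(issues, shares, "consumption.stove_profile")
    for (nm in names(cns$stove_profile)) {
      f <- cns$stove_profile[[nm]]
      issues <- check_ef(issues, f$ef,
                         paste0("consumption.stove_profile.", nm, ".ef"))
      if (f$efficiency <= 0 || f$efficiency > 1)
        issues <- add_issue(issues,
                            paste0("consumption.stove_profile.", nm, ".efficiency"),
                            "efficiency must lie in (0, 1]")
    }
    w <- cns$bms_waste_fraction
    wv <- if (is.list(w)) w$value else w
    if (is.null(wv) || wv < 0 || wv >= 1)
      issues <- add_issue(issues, "consumption.bms_waste_fraction",
                          "must lie in [0, 1)")
    items <- cns$diet$items
    if (length(items)) {
      issues <- check_mixture(issues,
                              vapply(items, `[[`, numeric(1), "share"),
                              "consumption.diet.items.share")
      for (i in seq_along(items)) {
        it <- items[[i]]
        issues <- check_ef(issues, it$ef_per_mj,
                           sprintf("consumption.diet.items[%d].ef_per_mj", i))
        if (it$household_waste < 0 || it$household_waste >= 1)
          issues <- add_issue(issues,
                              sprintf("consumption.diet.items[%d].household_waste", i),
                              "waste fraction must lie in [0, 1)")
        if (it$mass_per_mj < 0)
          issues <- add_issue(issues,
                              sprintf("consumption.diet.items[%d].mass_per_mj", i),
                              "must be >= 0")
        if (!it$category %in% c("plant", "animal"))
          issues <- add_issue(issues,
                              sprintf("consumption.diet.items[%d].category", i),
                              "category must be plant or animal")
      }
    } else {
      issues <- add_issue(issues, "consumption.diet", "diet has no items")
    }
    for (i in seq_along(cns$retail_transport_legs)) {
      leg <- cns$retail_transport_legs[[i]]
      if ((leg$distance_km %||% 0) < 0)
        issues <- add_issue(issues,
                            sprintf("consumption.retail_transport_legs[%d].distance_km", i),
                            "distance must be >= 0")
    }
    if ((cns$sterilisation_boil_factor %||% 1) <= 0)
      issues <- add_issue(issues, "consumption.sterilisation_boil_factor",
                          "must be > 0")
  }
  if (is.null(p) && is.null(cns))
    issues <- add_issue(issues, "role",
                        "scenario has neither production nor consumption data")
  issues
}

#' Is a scenario valid?
#' @param s a `bms_scenario`.
#' @return logical.
#' @export
is_valid_scenario <- function(s) nrow(validate_scenario(s)) == 0

unparse_ef <- function(ef) {
  out <- list(value = ef$value, unit = ef$unit, gas_shares = ef$gas_shares)
  if (!is.null(ef$distribution)) {
    d <- ef$distribution
    out$distribution <- Filter(Negate(is.null),
                               list(family = d$family, cv = d$cv,
                                    rel_min = d$rel_min, rel_max = d$rel_max,
                                    centre = d$centre))
  }
  if (isTRUE(ef$calibrated)) out$calibrated <- TRUE
  out
}

unparse_scenario <- function(s) {
  raw <- list(country = s$country, role = s$role)
  if (!is.null(s$production)) {
    p <- s$production
    p$raw_milk_ef <- unparse_ef(p$raw_milk_ef)
    p$electricity_ef <- unparse_ef(p$electricity_ef)
    p$heat_ef <- unparse_ef(p$heat_ef)
    p$oil_efs <- lapply(p$oil_efs, unparse_ef)
    p$packaging_efs <- lapply(p$packaging_efs, unparse_ef)
    p$sea_transport_ef <- unparse_ef(p$sea_transport_ef)
    p$chain_waste <- as.list(p$chain_waste)
    raw$production <- p
  }
  if (!is.null(s$consumption)) {
    cns <- s$consumption
    cns$stove_profile <- lapply(cns$stove_profile, function(f) {
      f$ef <- unparse_ef(f$ef); f
    })
    cns$diet$items <- lapply(cns$diet$items, function(it) {
      it$ef_per_mj <- unparse_ef(it$ef_per_mj); it
    })
    cns$bms_waste_fraction <- as.numeric(cns$bms_waste_fraction)
    raw$consumption <- cns
  }
  raw
}

#' Write a scenario to a YAML file
#'
#' Serialising then reloading with [read_scenario()] reproduces the scenario
#' field for field.
#'
#' @param s a `bms_scenario`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(s, path) {
  yaml::write_yaml(unparse_scenario(s), path, precision = 15)
  invisible(path)
}

#' Read a scenario from a YAML file
#' @param path scenario YAML file.
#' @return a `bms_scenario`.
#' @export
read_scenario <- function(path) load_scenario_file(path)

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

jitter_mixture <- function(shares) {
  v <- unlist(shares) * stats::rgamma(length(shares), shape = 4, rate = 4)
  v[v <= 0] <- 1e-6
  v <- v / sum(v)
  stats::setNames(as.list(v), names(shares))
}

#' Generate a synthetic scenario
#'
#' Draws a random but structurally valid scenario for property testing:
#' emission factors are drawn within three-fold of the range spanned by the
#' packaged defaults, mixtures are jittered and renormalised to one, waste
#' fractions stay in `[0, 1)`. Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param base optional scenario to perturb; defaults to a packaged scenario
#'   chosen by the seed.
#' @return a valid `bms_scenario` with role `both`.
#' @export
generate_synthetic_scenario <- function(seed, base = NULL) {
  set.seed(as.integer(seed))
  defaults <- default_scenarios()
  prods <- Filter(function(s) !is.null(s$production), defaults)
  cons <- Filter(function(s) !is.null(s$consumption), defaults)
  raw_vals <- vapply(prods, function(s) s$production$raw_milk_ef$value, numeric(1))
  if (is.null(base)) {
    pick_p <- prods[[sample(length(prods), 1)]]
    pick_c <- cons[[sample(length(cons), 1)]]
  } else {
    pick_p <- base
    pick_c <- base
  }
  p <- pick_p$production
  cns <- pick_c$consumption

  span <- function(vals) c(min(vals) / 3, max(vals) * 3)
  rr <- span(raw_vals)
  p$raw_milk_ef$value <- runif1(rr[1], rr[2])
  ev <- span(vapply(prods, function(s) s$production$electricity_ef$value, numeric(1)))
  p$electricity_ef$value <- runif1(ev[1], ev[2])
  hv <- span(vapply(prods, function(s) s$production$heat_ef$value, numeric(1)))
  p$heat_ef$value <- runif1(hv[1], hv[2])
  p$oil_blend <- jitter_mixture(p$oil_blend)
  p$oil_efs <- lapply(p$oil_efs, function(ef) {
    ef$value <- ef$value * runif1(1 / 3, 3); ef
  })
  p$packaging_mix <- jitter_mixture(p$packaging_mix)
  p$chain_waste <- stats::runif(length(p$chain_waste) %||% 1, 0, 0.3)
  if (!length(p$chain_waste)) p$chain_waste <- stats::runif(1, 0, 0.3)
  p$transport_legs <- lapply(p$transport_legs, function(leg) {
    leg$distance_km <- leg$distance_km * runif1(0.5, 2); leg
  })
  p$milk_meat_allocation <- runif1(0.88, 0.94)

  shares <- jitter_mixture(lapply(cns$stove_profile, `[[`, "share"))
  for (nm in names(cns$stove_profile)) {
    cns$stove_profile[[nm]]$share <- shares[[nm]]
    cns$stove_profile[[nm]]$ef$value <-
      cns$stove_profile[[nm]]$ef$value * runif1(1 / 3, 3)
    cns$stove_profile[[nm]]$efficiency <- runif1(0.1, 0.9)
  }
  dshares <- jitter_mixture(lapply(cns$diet$items, `[[`, "share"))
  for (i in seq_along(cns$diet$items)) {
    cns$diet$items[[i]]$share <- dshares[[i]]
    cns$diet$items[[i]]$ef_per_mj$value <-
      cns$diet$items[[i]]$ef_per_mj$value * runif1(1 / 3, 3)
    cns$diet$items[[i]]$household_waste <- runif1(0, 0.4)
  }
  cns$bms_waste_fraction <- runif1(0, 0.4)
  cns$production_country <- NULL  # self-supplied

  s <- structure(list(country = sprintf("Synthetic-%d", as.integer(seed)),
                      role = "both", production = p, consumption = cns),
                 class = "bms_scenario")
  rep <- validate_scenario(s)
  if (nrow(rep) > 0)
    stop("internal error: synthetic scenario invalid: ",
         paste(rep$field, collapse = ", "))
  s
}
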