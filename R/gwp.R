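# GWP100 characterisation sets and re-characterisation of emission factors.
#
# All packaged emission factors are expressed in CO2-equivalents under the
# IPCC AR4 factors (CH4 = 25, N2O = 298), the reference set of the underlying
# inventory data. Switching to another set rescales the CH4 and N2O parts of
# each factor through its gas shares.

GWP_REFERENCE <- list(ch4 = 25, n2o = 298)

GWP_SETS <- list(
  "AR4" = list(label = "AR4", ch4 = 25, n2o = 298),
  "AR5" = list(label = "AR5", ch4 = 28, n2o = 265),
  "AR5-feedback" = list(label = "AR5-feedback", ch4 = 34, n2o = 298)
)

#' GWP100 characterisation set
#'
#' Returns one of the packaged GWP100 factor sets: `"AR4"` (CH4 25, N2O 298),
#' `"AR5"` (CH4 28, N2O 265) or `"AR5-feedback"` (CH4 34 including
#' climate-carbon feedbacks, N2O 298).
#'
#' @param label set label.
#' @return list with `label`, `ch4` and `n2o` (kg CO2e per kg gas).
#' @export
gwp_set <- function(label = c("AR4", "AR5", "AR5-feedback")) {
  label <- match.arg(label)
  structure(GWP_SETS[[label]], class = "bms_gwp")
}

as_gwp <- function(x) {
  if (inherits(x, "bms_gwp")) return(x)
  if (is.character(x)) return(gwp_set(x))
  stopifnot(is.list(x), is.numeric(x$ch4), is.numeric(x$n2o),
            x$ch4 > 0, x$n2o > 0)
  structure(list(label = x$label %||% "custom", ch4 = x$ch4, n2o = x$n2o),
            class = "bms_gwp")
}

#' Re-characterisation multiplier for an emission factor
#'
#' Given the shares of a CO2e value attributable to CO2, CH4 and N2O under
#' the AR4 reference set, returns the factor by which the value changes when
#' characterised under another GWP set.
#'
#' @param gas_shares named list/vector with `co2`, `ch4`, `n2o` shares
#'   (summing to 1).
#' @param gwp a [gwp_set()] or label.
#' @return numeric multiplier (1 under AR4).
#' @export
gwp_adjustment <- function(gas_shares, gwp = gwp_set("AR4")) {
  gwp <- as_gwp(gwp)
  g <- unlist(gas_shares)[c("co2", "ch4", "n2o")]
  g[is.na(g)] <- 0
  if (abs(sum(g) - 1) > 1e-9) stop("gas shares must sum to 1")
  unname(g["co2"] + g["ch4"] * gwp$ch4 / GWP_REFERENCE$ch4 +
           g["n2o"] * gwp$n2o / GWP_REFERENCE$n2o)
}

#' Emission factor
#'
#' A CO2e emission factor with its unit, the shares of the CO2e value
#' attributable to each greenhouse gas under the AR4 reference
#' characterisation, and an optional uncertainty distribution.
#'
#' @param value non-negative factor value (kg CO2e per unit).
#' @param unit character unit, e.g. `"kg CO2e per kg ECM"`.
#' @param gas_shares named shares for `co2`, `ch4`, `n2o` (sum to 1); defaults
#'   to pure CO2.
#' @param distribution optional [dist_spec()].
#' @param calibrated logical flag marking values calibrated against the
#'   printed result tables rather than taken directly from printed inputs.
#' @return object of class `bms_ef`.
#' @export
emission_factor <- function(value, unit = "kg CO2e per unit",
                            gas_shares = c(co2 = 1, ch4 = 0, n2o = 0),
                            distribution = NULL, calibrated = FALSE) {
  stopifnot(is.numeric(value), length(value) == 1, value >= 0)
  g <- unlist(gas_shares)
  if (any(g < -1e-12) || any(g > 1 + 1e-12) || abs(sum(g) - 1) > 1e-9)
    stop("gas_shares must lie in [0, 1] and sum to 1")
  structure(list(value = value, unit = unit,
                 gas_shares = as.list(g),
                 distribution = if (is.null(distribution)) NULL else as_dist_spec(distribution),
                 calibrated = isTRUE(calibrated)),
            class = "bms_ef")
}

as_ef <- function(x, unit = "kg CO2e per unit") {
  if (inherits(x, "bms_ef")) return(x)
  if (is.numeric(x) && length(x) == 1) return(emission_factor(x, unit))
  emission_factor(value = x$value, unit = x$unit %||% unit,
                  gas_shares = x$gas_shares %||% c(co2 = 1, ch4 = 0, n2o = 0),
                  distribution = x$distribution,
                  calibrated = x$calibrated %||% FALSE)
}

#' Characterised value of an emission factor
#'
#' @param ef a [emission_factor()].
#' @param gwp a [gwp_set()] or label; AR4 returns the stored value.
#' @return numeric value under the requested characterisation.
#' @export
ef_value <- function(ef, gwp = gwp_set("AR4")) {
  ef <- as_ef(ef)
  ef$value * gwp_adjustment(ef$gas_shares, gwp)
}

#' @export
print.bms_ef <- function(x, ...) {
  cat(format(x$value), x$unit,
      if (isTRUE(x$calibrated)) "(calibrated)" else "", "\n")
  invisible(x)
}
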