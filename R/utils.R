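# Small shared helpers: rounding to printed precision, mixture checks,
# stage-breakdown container.

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching the way the
#' result tables are printed (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Round to significant figures, half away from zero
#'
#' @param x numeric vector.
#' @param digits significant figures (default 2, the table style used
#'   throughout the reported results).
#' @return rounded numeric vector.
#' @export
signif_half_up <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  mag <- floor(log10(abs(x[nz])))
  out[nz] <- round_half_up(x[nz], digits - 1 - mag)
  out
}

#' Format a value to two significant figures as printed in the result tables
#' @param x numeric vector.
#' @param digits significant figures.
#' @return character vector.
#' @export
format_sig <- function(x, digits = 2) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(NA_character_)
    r <- signif_half_up(v, digits)
    if (r == 0) return("0")
    mag <- floor(log10(abs(r)))
    dec <- max(0, digits - 1 - mag)
    format(r, nsmall = dec, trim = TRUE, scientific = FALSE)
  }, character(1))
}

# mixture (shares) must sum to 1 within tolerance
is_mixture <- function(x, tol = 1e-9) {
  all(x >= -tol) && abs(sum(x) - 1) <= tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-stage footprint breakdown
#'
#' Ordered named stage contributions (kg CO2e per kg BMS) whose total is the
#' sum of the stages, the shape of the production and consumption result
#' tables.
#'
#' @param stages named numeric vector of non-negative stage contributions.
#' @param ... extra metadata stored as attributes (scenario, basis, gwp).
#' @return object of class `bms_stages`.
#' @export
stage_breakdown <- function(stages, ...) {
  stopifnot(is.numeric(stages), !is.null(names(stages)), all(nzchar(names(stages))))
  if (any(stages < -1e-12)) stop("stage contributions must be non-negative")
  obj <- structure(as.list(stages), class = "bms_stages")
  meta <- list(...)
  for (nm in names(meta)) attr(obj, nm) <- meta[[nm]]
  obj
}

#' Stage values of a breakdown
#' @param x a `bms_stages` object.
#' @return named numeric vector.
#' @export
stages <- function(x) {
  stopifnot(inherits(x, "bms_stages"))
  unlist(x)
}

#' Total footprint of a breakdown
#' @param x a `bms_stages` object.
#' @return numeric total (sum of stages).
#' @export
total_cfp <- function(x) sum(stages(x))

#' @export
print.bms_stages <- function(x, ...) {
  sc <- attr(x, "scenario")
  if (!is.null(sc)) cat("Scenario:", sc, "\n")
  b <- attr(x, "basis")
  if (!is.null(b)) cat("Allocation basis:", b, "\n")
  v <- stages(x)
  cat(paste0(format(names(v), width = max(nchar(names(v)))), "  ",
             format_sig(v), " kg CO2e/kg BMS", collapse = "\n"), "\n")
  cat("Total:", format_sig(sum(v)), "kg CO2e/kg BMS\n")
  invisible(x)
}
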