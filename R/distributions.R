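# Uncertainty grammar for Monte Carlo propagation: point values with an
# attached distribution family. CV-parameterised normal and lognormal
# families, and triangular families given as relative offsets around the
# point value.

#' Distribution specification
#'
#' Describes the uncertainty attached to a point-valued model parameter.
#' Four families are supported:
#' \describe{
#'   \item{point}{no uncertainty, all draws equal the point value;}
#'   \item{normal_cv}{normal with mean at the point value and standard
#'     deviation `cv`/100 times the point value;}
#'   \item{lognormal_cv}{lognormal parameterised so the arithmetic mean is
#'     the point value and the coefficient of variation is `cv`/100;}
#'   \item{triangular}{triangular with support given by relative offsets
#'     `rel_min` (<= 0) and `rel_max` (>= 0).}
#' }
#'
#' For triangular distributions `centre` chooses where the point value sits:
#' `"mode"` places the mode at the point value (the support is then
#' `point * (1 + rel_min)` to `point * (1 + rel_max)`, so asymmetric offsets
#' shift the mean away from the point value); `"mean"` rescales the support
#' so the arithmetic mean of the draws equals the point value while the
#' relative span of the triangle is preserved. For symmetric offsets the two
#' coincide.
#'
#' @param family one of `"point"`, `"normal_cv"`, `"lognormal_cv"`,
#'   `"triangular"`.
#' @param cv coefficient of variation in percent (cv families).
#' @param rel_min,rel_max relative offsets for the triangular family.
#' @param centre `"mode"` or `"mean"` (triangular only).
#' @return object of class `bms_dist`.
#' @export
dist_spec <- function(family = c("point", "normal_cv", "lognormal_cv", "triangular"),
                      cv = NULL, rel_min = NULL, rel_max = NULL,
                      centre = c("mode", "mean")) {
  family <- match.arg(family)
  centre <- match.arg(centre)
  if (family %in% c("normal_cv", "lognormal_cv")) {
    stopifnot(is.numeric(cv), length(cv) == 1, cv >= 0)
  }
  if (family == "triangular") {
    stopifnot(is.numeric(rel_min), is.numeric(rel_max),
              rel_min <= 0, rel_max >= 0)
  }
  structure(list(family = family, cv = cv, rel_min = rel_min,
                 rel_max = rel_max, centre = centre),
            class = "bms_dist")
}

as_dist_spec <- function(x) {
  if (inherits(x, "bms_dist")) return(x)
  if (is.null(x)) return(dist_spec("point"))
  dist_spec(family = x$family %||% "point", cv = x$cv,
            rel_min = x$rel_min, rel_max = x$rel_max,
            centre = x$centre %||% "mode")
}

# triangular support for a unit point value
tri_support <- function(spec) {
  m <- 1
  a <- 1 + spec$rel_min
  b <- 1 + spec$rel_max
  if (identical(spec$centre, "mean")) {
    # rescale so (a + m + b)/3 == 1 while keeping relative span
    s <- 3 / (a + m + b)
    a <- a * s; m <- m * s; b <- b * s
  }
  c(a = a, mode = m, b = b)
}

rtriangular <- function(n, a, m, b) {
  u <- stats::runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Draw from a distribution specification
#'
#' Draws `n` multiplicative realisations of a parameter around its point
#' value. Deterministic for a fixed seed.
#'
#' @param spec a [dist_spec()] (or a plain list with the same fields).
#' @param point_value the point value of the parameter (must be positive for
#'   the lognormal family).
#' @param n number of draws.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so that joint Monte Carlo sampling stays reproducible from a
#'   single seed).
#' @return numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, point_value, n, seed = NULL) {
  spec <- as_dist_spec(spec)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  switch(spec$family,
    point = rep(point_value, n),
    normal_cv = stats::rnorm(n, mean = point_value,
                             sd = spec$cv / 100 * abs(point_value)),
    lognormal_cv = {
      if (point_value <= 0) stop("lognormal_cv requires a positive point value")
      cv <- spec$cv / 100
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(point_value) - sdlog^2 / 2
      stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    },
    triangular = {
      s <- tri_support(spec)
      point_value * rtriangular(n, s["a"], s["mode"], s["b"])
    })
}

# analytic mean multiplier of a spec (used for documentation and tests)
dist_mean_multiplier <- function(spec) {
  spec <- as_dist_spec(spec)
  if (spec$family != "triangular") return(1)
  s <- tri_support(spec)
  unname((s["a"] + s["mode"] + s["b"]) / 3)
}
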