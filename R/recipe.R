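# BMS recipe model: ingredient specifications, per-100 kJ nutrient profile,
# Codex Alimentarius compliance, and rejection sampling of the feasible
# recipe space for the recipe Monte Carlo.
#
# The functional unit is 1 kg of powder at 21.7 kJ/g. Recipes are expressed
# as fractions of total solids over the four main ingredients; vitamins and
# minerals (~2% of solids) are excluded from the recipe mass balance and
# handled as a separate scenario add-on.

RECIPE_INGREDIENTS <- c("skimmed_milk", "whey_protein_concentrate",
                        "lactose", "vegetable_oil")

#' Default ingredient specifications
#'
#' Reads the packaged ingredient composition table (g nutrient per g dry
#' ingredient, whey share of protein, and gross energy density in kJ/g).
#' The compositions are calibrated so the baseline recipe reproduces the
#' reference nutrient profile (protein 0.60, carbohydrate 2.69, fat 1.19,
#' ash 0.08 g/100 kJ at 21.7 kJ/g with 65% of protein from whey).
#'
#' @param path optional path to an alternative CSV with the same columns.
#' @return data.frame with one row per ingredient.
#' @export
default_ingredients <- function(path = NULL) {
  path <- path %||% system.file("extdata", "config", "shared",
                                "ingredients.csv", package = "bmslca")
  ing <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "protein", "fat", "carbohydrate", "ash",
           "whey_share_of_protein", "energy_density")
  if (!all(req %in% names(ing))) stop("ingredient table missing columns")
  comp <- ing$protein + ing$fat + ing$carbohydrate + ing$ash
  if (any(ing$protein < 0 | ing$fat < 0 | ing$carbohydrate < 0 | ing$ash < 0) ||
      any(comp > 1 + 1e-9))
    stop("ingredient component fractions must be >= 0 and sum to <= 1")
  if (any(ing$energy_density <= 0)) stop("energy_density must be positive")
  ing
}

#' BMS recipe
#'
#' A recipe is a set of non-negative ingredient fractions of total solids
#' summing to 1.
#'
#' @param fractions named numeric vector over (a subset of) the ingredients
#'   `skimmed_milk`, `whey_protein_concentrate`, `lactose`, `vegetable_oil`.
#' @return object of class `bms_recipe`.
#' @export
recipe <- function(fractions) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (!is_mixture(fractions)) stop("recipe fractions must be >= 0 and sum to 1")
  full <- stats::setNames(numeric(length(RECIPE_INGREDIENTS)), RECIPE_INGREDIENTS)
  unknown <- setdiff(names(fractions), RECIPE_INGREDIENTS)
  if (length(unknown)) full[unknown] <- 0  # keep names, checked at profile time
  full[names(fractions)] <- fractions
  structure(full, class = "bms_recipe")
}

#' Baseline recipe
#'
#' The assumed baseline: 15% skimmed milk solids, 10% whey protein
#' concentrate, 50% lactose, 25% vegetable oils (fractions of total solids).
#'
#' @return a [recipe()].
#' @export
baseline_recipe <- function() {
  recipe(c(skimmed_milk = 0.15, whey_protein_concentrate = 0.10,
           lactose = 0.50, vegetable_oil = 0.25))
}

#' Nutrient profile of a recipe
#'
#' Mass-weighted ingredient composition divided by the recipe's energy
#' density, giving g per 100 kJ. The energy density is the mass-weighted mean
#' of the ingredient energy densities.
#'
#' @param r a [recipe()].
#' @param ingredients ingredient table, see [default_ingredients()].
#' @return object of class `bms_profile` with fields `protein`,
#'   `carbohydrate`, `fat`, `ash` (g/100 kJ), `whey_fraction` and
#'   `energy_density` (kJ/g).
#' @export
nutrient_profile <- function(r, ingredients = default_ingredients()) {
  fr <- unclass(r)
  missing <- setdiff(names(fr)[fr > 0], ingredients$name)
  if (length(missing))
    stop("no ingredient specification for: ", paste(missing, collapse = ", "))
  idx <- match(names(fr), ingredients$name)
  keep <- !is.na(idx)
  fr <- fr[keep]; idx <- idx[keep]
  ing <- ingredients[idx, ]
  e <- sum(fr * ing$energy_density)            # kJ per g solids
  per_g <- function(col) sum(fr * ing[[col]])  # g per g solids
  protein_g <- per_g("protein")
  whey_g <- sum(fr * ing$protein * ing$whey_share_of_protein)
  structure(list(
    protein = protein_g / e * 100,
    carbohydrate = per_g("carbohydrate") / e * 100,
    fat = per_g("fat") / e * 100,
    ash = per_g("ash") / e * 100,
    whey_fraction = if (protein_g > 0) whey_g / protein_g else 0,
    energy_density = e
  ), class = "bms_profile")
}

#' @export
print.bms_profile <- function(x, ...) {
  cat(sprintf("protein %.2f, carbohydrate %.2f, fat %.2f, ash %.2f g/100 kJ\n",
              x$protein, x$carbohydrate, x$fat, x$ash))
  cat(sprintf("whey fraction of protein %.2f, energy density %.1f kJ/g\n",
              x$whey_fraction, x$energy_density))
  invisible(x)
}

#' Codex Alimentarius composition limits
#'
#' Permitted ranges for infant formula (g/100 kJ) and the minimum share of
#' protein from whey.
#'
#' @param protein,carbohydrate,fat numeric `c(min, max)` ranges.
#' @param whey_min minimum whey fraction of protein.
#' @return object of class `bms_codex`.
#' @export
codex_limits <- function(protein = c(0.45, 0.70),
                         carbohydrate = c(2.30, 3.30),
                         fat = c(1.05, 1.40),
                         whey_min = 0.50) {
  for (rng in list(protein, carbohydrate, fat))
    stopifnot(length(rng) == 2, rng[1] <= rng[2])
  structure(list(protein = protein, carbohydrate = carbohydrate,
                 fat = fat, whey_min = whey_min), class = "bms_codex")
}

#' Check a nutrient profile against Codex limits
#'
#' @param p a [nutrient_profile()].
#' @param limits a [codex_limits()].
#' @return data.frame listing each violated bound (zero rows when compliant),
#'   with attribute `pass`.
#' @export
validate_codex <- function(p, limits = codex_limits()) {
  viol <- list()
  for (nut in c("protein", "carbohydrate", "fat")) {
    rng <- limits[[nut]]
    v <- p[[nut]]
    if (v < rng[1]) viol[[length(viol) + 1]] <-
        data.frame(nutrient = nut, bound = "min", limit = rng[1], value = v)
    if (v > rng[2]) viol[[length(viol) + 1]] <-
        data.frame(nutrient = nut, bound = "max", limit = rng[2], value = v)
  }
  if (p$whey_fraction < limits$whey_min) viol[[length(viol) + 1]] <-
      data.frame(nutrient = "whey_fraction", bound = "min",
                 limit = limits$whey_min, value = p$whey_fraction)
  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(nutrient = character(), bound = character(),
               limit = numeric(), value = numeric())
  attr(out, "pass") <- nrow(out) == 0
  out
}

#' Is a profile Codex-compliant?
#' @param p a [nutrient_profile()].
#' @param limits a [codex_limits()].
#' @return logical.
#' @export
codex_pass <- function(p, limits = codex_limits()) {
  attr(validate_codex(p, limits), "pass")
}

# vectorised feasibility over simplex coordinates (columns of a matrix),
# shared by the sampler and by grid-based diagnostics
codex_feasible_fractions <- function(frac_matrix, ingredients, limits) {
  idx <- match(RECIPE_INGREDIENTS, ingredients$name)
  ing <- ingredients[idx, ]
  e <- as.vector(frac_matrix %*% ing$energy_density)
  protein <- as.vector(frac_matrix %*% ing$protein) / e * 100
  carb <- as.vector(frac_matrix %*% ing$carbohydrate) / e * 100
  fat <- as.vector(frac_matrix %*% ing$fat) / e * 100
  whey <- as.vector(frac_matrix %*% (ing$protein * ing$whey_share_of_protein))
  whey_frac <- ifelse(protein > 0, whey / (protein * e / 100), 0)
  protein >= limits$protein[1] & protein <= limits$protein[2] &
    carb >= limits$carbohydrate[1] & carb <= limits$carbohydrate[2] &
    fat >= limits$fat[1] & fat <= limits$fat[2] &
    whey_frac >= limits$whey_min
}

#' Sample Codex-compliant recipes
#'
#' Uniform rejection sampling over the 3-simplex of solids fractions:
#' candidate recipes are drawn uniformly from the simplex and kept when their
#' nutrient profile passes [validate_codex()]. Deterministic for a fixed
#' seed.
#'
#' @param n number of recipes to return.
#' @param seed integer seed.
#' @param ingredients ingredient table.
#' @param limits a [codex_limits()].
#' @param max_batches bounded attempt budget; an infeasibility error is
#'   raised if no compliant recipe is found after `max_batches` batches of
#'   `n` candidates.
#' @return list of [recipe()] objects with attribute `acceptance_rate` (the
#'   fraction of candidates accepted).
#' @export
sample_recipes <- function(n, seed, ingredients = default_ingredients(),
                           limits = codex_limits(), max_batches = 2000) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  kept <- matrix(numeric(0), ncol = 4)
  tried <- 0L
  batches <- 0L
  while (nrow(kept) < n) {
    batches <- batches + 1L
    if (batches > max_batches)
      stop("feasible recipe region appears empty under the given ",
           "ingredient specifications (attempt budget exhausted)")
    m <- max(n, 1000L)
    # uniform on the simplex via normalised exponentials
    g <- matrix(stats::rexp(m * 4), ncol = 4)
    g <- g / rowSums(g)
    ok <- codex_feasible_fractions(g, ingredients, limits)
    tried <- tried + m
    kept <- rbind(kept, g[ok, , drop = FALSE])
  }
  accepted <- nrow(kept)
  kept <- kept[seq_len(n), , drop = FALSE]
  out <- lapply(seq_len(n), function(i)
    recipe(stats::setNames(kept[i, ], RECIPE_INGREDIENTS)))
  attr(out, "acceptance_rate") <- accepted / tried
  out
}
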