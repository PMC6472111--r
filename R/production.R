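# Cradle-to-gate footprint of producing and packaging 1 kg of BMS powder
# (CFP_Prod): raw milk, vegetable oils, processing energy, packaging and
# transport stages.

#' Chain-waste multiplier
#'
#' Losses along the supply chain inflate the upstream quantity needed per
#' unit of final product: `prod(1 / (1 - w_i))`.
#'
#' @param waste_fractions ordered numeric vector of per-stage waste
#'   fractions, each in `[0, 1)`.
#' @return multiplier `>= 1`.
#' @export
waste_multiplier <- function(waste_fractions) {
  if (!length(waste_fractions)) return(1)
  if (any(waste_fractions < 0) || any(waste_fractions >= 1))
    stop("waste fractions must lie in [0, 1)")
  prod(1 / (1 - waste_fractions))
}

#' Footprint of a vegetable oil blend
#'
#' Share-weighted mean of the per-oil emission factors. The per-oil factors
#' already embed the economic allocation between oil and press residues and
#' are taken as inputs.
#'
#' @param blend named shares summing to 1.
#' @param oil_efs named list of [emission_factor()]s covering every oil in
#'   the blend.
#' @param gwp GWP characterisation set.
#' @return kg CO2e per kg oil blend.
#' @export
oil_blend_cfp <- function(blend, oil_efs, gwp = gwp_set("AR4")) {
  shares <- unlist(blend)
  if (!is_mixture(shares)) stop("oil blend shares must sum to 1")
  unknown <- setdiff(names(shares), names(oil_efs))
  if (length(unknown)) stop("unknown oil in blend: ",
                            paste(unknown, collapse = ", "))
  sum(shares * vapply(names(shares),
                      function(nm) ef_value(oil_efs[[nm]], gwp), numeric(1)))
}

# Internal vectorised stage computation. `mult` entries may be numeric
# vectors (Monte Carlo draws); all stage outputs broadcast accordingly.
production_stage_values <- function(s, r = baseline_recipe(),
                                    basis = "dry_mass", gwp = gwp_set("AR4"),
                                    process = process_config(),
                                    ingredients = default_ingredients(),
                                    mult = list(), tree = NULL, burden = NULL) {
  p <- s$production
  if (is.null(p)) stop("scenario '", s$country, "' has no production role")
  m_raw <- mult$raw_milk_ef %||% 1
  m_oil <- mult$oil_ef %||% 1
  m_el <- mult$electricity_use %||% 1
  m_h <- mult$heat_use %||% 1

  if (is.null(tree))
    tree <- dairy_mass_balance(r, process, chain_waste = p$chain_waste,
                               ingredients = ingredients)
  if (is.null(burden)) burden <- allocated_burden(tree, basis)

  raw_milk <- ef_value(p$raw_milk_ef, gwp) * burden$raw_milk * m_raw

  oil_mass <- unclass(r)[["vegetable_oil"]]
  oil_cfp <- oil_blend_cfp(p$oil_blend, p$oil_efs, gwp)
  oil_transport <- oil_mass * p$oil_sea_distance_km *
    ef_value(p$sea_transport_ef, gwp) / 1000
  vegetable_oils <- oil_mass * oil_cfp * m_oil + oil_transport

  processing <- burden$electricity * m_el * ef_value(p$electricity_ef, gwp) +
    burden$heat * m_h * ef_value(p$heat_ef, gwp)

  mix <- unlist(p$packaging_mix)
  packaging <- sum(vapply(names(mix), function(nm)
    mix[[nm]] * p$packaging_masses[[nm]] * ef_value(p$packaging_efs[[nm]], gwp),
    numeric(1)))

  transport <- 0
  for (leg in p$transport_legs) {
    mass <- switch(leg$mass_basis,
      raw_milk = tree$raw_milk_input,
      whey = tree$streams$wet_mass[tree$streams$name == "whey"],
      dry_ingredients = sum(tree$streams$dry_mass[
        tree$streams$name %in% c("wpc", "lactose_powder")]),
      stop("unknown transport mass basis: ", leg$mass_basis))
    transport <- transport + mass * leg$distance_km * leg$ef / 1000
  }

  stages <- list(raw_milk = raw_milk, vegetable_oils = vegetable_oils,
                 processing = processing,
                 packaging = packaging + 0 * m_raw,
                 transport = transport + 0 * m_raw)
  if (isTRUE(p$include_luc)) {
    blend <- unlist(p$oil_blend)
    luc <- oil_mass * sum(blend * vapply(names(blend), function(nm)
      p$luc_factors[[nm]] %||% 0, numeric(1)))
    stages$land_use_change <- luc + 0 * m_raw
  }
  if (!is.null(p$vitamin_addon)) {
    stages$vitamins <- p$vitamin_addon$mass_fraction * p$vitamin_addon$ef +
      0 * m_raw
  }
  attr(stages, "tree") <- tree
  attr(stages, "burden") <- burden
  stages
}

#' Cradle-to-gate production footprint (CFP_Prod)
#'
#' Computes the per-stage footprint of producing and packaging 1 kg of BMS
#' powder up to the factory gate: raw milk (allocated through the dairy
#' mass balance and inflated by chain waste), vegetable oils (blend plus sea
#' transport), processing energy (allocated electricity and heat), packaging
#' (tin can / bag-in-box mix) and transport of ingredients between plants.
#'
#' @param s a production (or `both`) scenario.
#' @param r a [recipe()]; defaults to the baseline recipe.
#' @param basis allocation basis; defaults to the scenario's
#'   `allocation_basis` or `"dry_mass"`.
#' @param gwp GWP set; defaults to the scenario's `gwp` or AR4.
#' @param process,ingredients shared configuration.
#' @return a [stage_breakdown()] with attributes `tree` and `burden`.
#' @export
cfp_production <- function(s, r = baseline_recipe(), basis = NULL, gwp = NULL,
                           process = process_config(),
                           ingredients = default_ingredients()) {
  basis <- basis %||% s$allocation_basis %||% "dry_mass"
  gwp <- as_gwp(gwp %||% s$gwp %||% "AR4")
  st <- production_stage_values(s, r, basis, gwp, process, ingredients)
  stage_breakdown(vapply(st, function(x) x[1], numeric(1)),
                  scenario = s$country, basis = basis, gwp = gwp$label,
                  tree = attr(st, "tree"), burden = attr(st, "burden"))
}
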