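# Dairy processing mass balance and co-product allocation.
#
# The processing chain is: raw milk is skimmed (cream is a co-product); part
# of the skim milk goes directly into the wet mix, the rest is used for
# cheese-making (cheese curd is a co-product) whose whey is separated into
# whey protein concentrate and lactose powder (a mineral-rich permeate
# residue remains); the dairy ingredients are wet-mixed with the oil blend
# and spray-dried into 1 kg of powder.
#
# Raw-milk and shared process-energy burdens are allocated among co-products
# at each separation step by a chosen basis (dry mass by default; fat plus
# protein, energy content or economic value as alternatives), composing
# multiplicatively along the tree. Dedicated energy (wet mix and spray
# drying) is assigned entirely to the product being processed.

#' Co-product stream
#'
#' One output stream of a processing step with the properties used by the
#' allocation bases.
#'
#' @param name stream name.
#' @param wet_mass,dry_mass masses in kg (dry <= wet).
#' @param fat,protein component masses in kg (fat + protein <= dry).
#' @param energy gross energy in MJ.
#' @param price currency per kg dry matter.
#' @param destined_for_bms does this stream end up in the BMS?
#' @return a one-row data.frame of class `bms_stream`.
#' @export
co_product_stream <- function(name, wet_mass, dry_mass, fat = 0, protein = 0,
                              energy = 0, price = 0, destined_for_bms = FALSE) {
  stopifnot(wet_mass >= 0, dry_mass >= 0, fat >= 0, protein >= 0,
            energy >= 0, price >= 0)
  if (dry_mass > wet_mass + 1e-9) stop("dry_mass must not exceed wet_mass")
  if (fat + protein > dry_mass + 1e-9) stop("fat + protein must not exceed dry_mass")
  out <- data.frame(name = name, wet_mass = wet_mass, dry_mass = dry_mass,
                    fat = fat, protein = protein, energy = energy,
                    price = price, destined_for_bms = destined_for_bms,
                    stringsAsFactors = FALSE)
  class(out) <- c("bms_stream", class(out))
  out
}

#' Processing step
#'
#' @param name step name.
#' @param inputs,outputs character vectors of stream names.
#' @param electricity,heat energy use in MJ.
#' @param dedicated_to stream name the energy is dedicated to, or `NA` for
#'   shared energy (allocated by the same basis as the raw milk).
#' @return list of class `bms_step`.
#' @export
process_step <- function(name, inputs, outputs, electricity = 0, heat = 0,
                         dedicated_to = NA_character_) {
  stopifnot(electricity >= 0, heat >= 0)
  structure(list(name = name, inputs = inputs, outputs = outputs,
                 electricity = electricity, heat = heat,
                 dedicated_to = dedicated_to),
            class = "bms_step")
}

ALLOCATION_BASES <- c("dry_mass", "fat_protein", "energy", "economic")

basis_property <- function(streams, basis) {
  switch(basis,
    dry_mass = streams$dry_mass,
    fat_protein = streams$fat + streams$protein,
    energy = streams$energy,
    economic = streams$price * streams$dry_mass,
    stop("unknown allocation basis: ", basis))
}

#' Allocation factors over co-product streams
#'
#' `fraction_i = property_i / sum(property_j)` where the property is dry
#' mass, fat + protein, energy content, or economic value (price times dry
#' mass) according to the basis.
#'
#' @param streams data.frame of streams (rows) as built by
#'   [co_product_stream()] / [dairy_mass_balance()].
#' @param basis one of `"dry_mass"`, `"fat_protein"`, `"energy"`,
#'   `"economic"`.
#' @return named numeric vector of fractions summing to 1.
#' @export
allocation_factors <- function(streams, basis = "dry_mass") {
  basis <- match.arg(basis, ALLOCATION_BASES)
  prop <- basis_property(streams, basis)
  if (all(prop <= 0)) stop("allocation undefined: all streams have zero ",
                           basis, " value")
  stats::setNames(prop / sum(prop), streams$name)
}

#' Dairy mass balance for a recipe
#'
#' Builds the linked processing tree sized so that it delivers exactly the
#' recipe's dairy ingredient masses per kg BMS, inflated by the chain-waste
#' multiplier. The cheese-milk quantity is set by the binding whey component
#' (lactose, whey protein or fat); surplus whey components leave in the
#' permeate.
#'
#' @param r a [recipe()].
#' @param process process configuration, see [process_config()].
#' @param chain_waste ordered per-stage waste fractions in `[0, 1)` applied
#'   as a multiplier `prod(1/(1-w))` to the dairy ingredient demands.
#' @param ingredients ingredient table (for the WPC and lactose-powder
#'   compositions).
#' @return object of class `bms_process_tree`.
#' @export
dairy_mass_balance <- function(r, process = process_config(),
                               chain_waste = numeric(),
                               ingredients = default_ingredients()) {
  fr <- unclass(r)
  m <- waste_multiplier(chain_waste)
  r_sm <- fr[["skimmed_milk"]] * m
  r_wpc <- fr[["whey_protein_concentrate"]] * m
  r_lact <- fr[["lactose"]] * m
  r_oil <- fr[["vegetable_oil"]]

  mc <- process$milk_composition
  Ff <- mc$fat; P <- mc$protein; L <- mc$lactose; A <- mc$ash
  sigma <- Ff + P + L + A
  phi_f <- mc$skim_fat_dm_fraction
  s <- (sigma - Ff) / (1 - phi_f)          # skim DM per kg raw milk
  cream_dm_per_milk <- Ff - phi_f * s
  phi_p <- P / s; phi_l <- L / s; phi_a <- A / s
  wheyp_share <- mc$whey_protein_share

  ws <- process$whey_split
  w_fat <- ws$fat_to_whey * phi_f
  w_prot <- wheyp_share * phi_p
  w_lact <- ws$lactose_to_whey * phi_l
  w_ash <- ws$ash_to_whey * phi_a
  w_dm <- w_fat + w_prot + w_lact + w_ash

  wpc_spec <- ingredients[ingredients$name == "whey_protein_concentrate", ]
  lact_spec <- ingredients[ingredients$name == "lactose", ]
  need <- c(lactose = r_lact * lact_spec$carbohydrate + r_wpc * wpc_spec$carbohydrate,
            whey_protein = r_wpc * wpc_spec$protein,
            fat = r_wpc * wpc_spec$fat,
            ash = r_lact * lact_spec$ash + r_wpc * wpc_spec$ash)
  supply <- c(lactose = w_lact, whey_protein = w_prot, fat = w_fat, ash = w_ash)
  ratio <- numeric(length(need))
  for (i in seq_along(need)) {
    if (need[i] <= 0) { ratio[i] <- 0; next }
    if (supply[i] <= 0)
      stop("infeasible composition: whey supplies no ", names(need)[i],
           " but the recipe demands it")
    ratio[i] <- need[i] / supply[i]
  }
  C <- max(ratio)                           # cheese-milk skim DM, kg
  W <- C * w_dm                             # whey DM, kg
  perm_dm <- W - (r_wpc + r_lact)
  if (perm_dm < -1e-9) stop("internal mass-balance error: negative permeate")
  perm_dm <- max(perm_dm, 0)

  skim_dm_total <- r_sm + C
  M <- skim_dm_total / s                    # raw milk, kg
  prices <- process$prices
  ec <- process$energy_coefficients
  energy_of <- function(fat, protein, lactose)
    ec$fat * fat + ec$protein * protein + ec$carbohydrate * lactose

  cream_dm <- M * cream_dm_per_milk
  cream_wet <- if (cream_dm > 0) cream_dm / process$cream_dm_content else 0
  skim_wet <- M - cream_wet
  skim_wet_bms <- if (skim_dm_total > 0) skim_wet * r_sm / skim_dm_total else 0
  skim_wet_cheese <- skim_wet - skim_wet_bms

  curd <- c(fat = (1 - ws$fat_to_whey) * phi_f * C,
            casein = (1 - wheyp_share) * phi_p * C,
            lactose = (1 - ws$lactose_to_whey) * phi_l * C,
            ash = (1 - ws$ash_to_whey) * phi_a * C)
  curd_dm <- sum(curd)
  whey_fat <- w_fat * C; whey_prot <- w_prot * C
  whey_lact <- w_lact * C; whey_ash <- w_ash * C
  perm <- c(fat = whey_fat - need[["fat"]],
            protein = whey_prot - need[["whey_protein"]],
            lactose = whey_lact - need[["lactose"]],
            ash = whey_ash - need[["ash"]])
  perm <- pmax(perm, 0)

  streams <- rbind(
    co_product_stream("raw_milk", M, M * sigma, M * Ff, M * P,
                      M * energy_of(Ff, P, L), 0),
    co_product_stream("cream", cream_wet, cream_dm, cream_dm, 0,
                      ec$fat * cream_dm, prices$cream),
    co_product_stream("skim_milk", skim_wet, skim_dm_total,
                      phi_f * skim_dm_total, phi_p * skim_dm_total,
                      energy_of(phi_f, phi_p, phi_l) * skim_dm_total,
                      prices$skim_milk),
    co_product_stream("skim_bms", skim_wet_bms, r_sm, phi_f * r_sm,
                      phi_p * r_sm, energy_of(phi_f, phi_p, phi_l) * r_sm,
                      prices$skim_milk, destined_for_bms = TRUE),
    co_product_stream("cheese_skim", skim_wet_cheese, C, phi_f * C,
                      phi_p * C, energy_of(phi_f, phi_p, phi_l) * C,
                      prices$skim_milk),
    co_product_stream("cheese_curd",
                      if (curd_dm > 0) curd_dm / process$curd_dm_content else 0,
                      curd_dm, curd[["fat"]], curd[["casein"]],
                      energy_of(curd[["fat"]], curd[["casein"]], curd[["lactose"]]),
                      prices$cheese_curd),
    co_product_stream("whey", if (W > 0) W / process$whey_dm_content else 0,
                      W, whey_fat, whey_prot,
                      energy_of(whey_fat, whey_prot, whey_lact),
                      prices$whey),
    co_product_stream("wpc", r_wpc, r_wpc, r_wpc * wpc_spec$fat,
                      r_wpc * wpc_spec$protein,
                      energy_of(wpc_spec$fat, wpc_spec$protein,
                                wpc_spec$carbohydrate) * r_wpc,
                      prices$whey_protein_concentrate,
                      destined_for_bms = TRUE),
    co_product_stream("lactose_powder", r_lact, r_lact, 0, 0,
                      energy_of(0, 0, lact_spec$carbohydrate) * r_lact,
                      prices$lactose, destined_for_bms = TRUE),
    co_product_stream("permeate",
                      if (perm_dm > 0) perm_dm / process$permeate_dm_content else 0,
                      perm_dm, perm[["fat"]], perm[["protein"]],
                      energy_of(perm[["fat"]], perm[["protein"]], perm[["lactose"]]),
                      prices$permeate),
    co_product_stream("bms", r_sm + r_wpc + r_lact + r_oil,
                      r_sm + r_wpc + r_lact + r_oil,
                      destined_for_bms = TRUE)
  )

  se <- process$step_energy
  steps <- list(
    process_step("skimming", "raw_milk", c("cream", "skim_milk"),
                 electricity = se$skimming$electricity * M,
                 heat = se$skimming$heat * M),
    process_step("skim_split", "skim_milk", c("skim_bms", "cheese_skim")),
    process_step("cheese_making", "cheese_skim", c("cheese_curd", "whey"),
                 electricity = se$cheese_making$electricity * C,
                 heat = se$cheese_making$heat * C),
    process_step("whey_separation", "whey",
                 c("wpc", "lactose_powder", "permeate"),
                 electricity = se$whey_separation$electricity * W,
                 heat = se$whey_separation$heat * W),
    process_step("wet_mix_spray_dry", c("skim_bms", "wpc", "lactose_powder"),
                 "bms",
                 electricity = se$wet_mix_spray_dry$electricity,
                 heat = se$wet_mix_spray_dry$heat,
                 dedicated_to = "bms")
  )

  structure(list(streams = streams, steps = steps,
                 raw_milk_input = M, waste_multiplier = m,
                 dairy_solids = r_sm + r_wpc + r_lact,
                 cheese_skim_dm = C, whey_dm = W),
            class = "bms_process_tree")
}

#' @export
print.bms_process_tree <- function(x, ...) {
  cat(sprintf("Dairy process tree: %.2f kg raw milk per kg BMS (%.2f kg dairy solids)\n",
              x$raw_milk_input, x$dairy_solids))
  print(process_tree_table(x))
  invisible(x)
}

#' Stream table of a process tree
#'
#' Renders the per-stream wet and dry masses (the numbers annotated on the
#' process flow diagram) as a data.frame.
#'
#' @param tree a [dairy_mass_balance()] result.
#' @return data.frame of streams.
#' @export
process_tree_table <- function(tree) {
  df <- tree$streams
  df[, c("name", "wet_mass", "dry_mass", "fat", "protein", "energy",
         "destined_for_bms")]
}

#' Serialise a process tree
#'
#' Writes the stream table and step energies as a YAML document.
#'
#' @param tree a [dairy_mass_balance()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_process_tree <- function(tree, path) {
  obj <- list(
    raw_milk_input = tree$raw_milk_input,
    waste_multiplier = tree$waste_multiplier,
    streams = lapply(seq_len(nrow(tree$streams)), function(i)
      as.list(tree$streams[i, ])),
    steps = lapply(tree$steps, function(st)
      list(name = st$name, inputs = st$inputs, outputs = st$outputs,
           electricity = st$electricity, heat = st$heat,
           dedicated_to = if (is.na(st$dedicated_to)) NULL else st$dedicated_to))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

# validate structural invariants of a tree (dry-mass conservation per step,
# no dangling intermediates); returns character vector of problems
check_process_tree <- function(tree, tol = 1e-6) {
  problems <- character()
  df <- tree$streams
  consumed <- unlist(lapply(tree$steps, `[[`, "inputs"))
  produced <- unlist(lapply(tree$steps, `[[`, "outputs"))
  for (st in tree$steps) {
    din <- sum(df$dry_mass[df$name %in% st$inputs])
    dout <- sum(df$dry_mass[df$name %in% st$outputs])
    extern <- if (st$name == "wet_mix_spray_dry")
      df$dry_mass[df$name == "bms"] - din else 0  # oil enters the wet mix
    if (abs(din + extern - dout) > tol)
      problems <- c(problems, paste0("dry mass not conserved at ", st$name))
  }
  referenced <- unique(c(consumed, produced))
  missing <- setdiff(referenced, df$name)
  if (length(missing))
    problems <- c(problems, paste0("dangling stream reference: ", missing))
  unstated <- setdiff(df$name, c(referenced))
  if (length(unstated))
    problems <- c(problems, paste0("stream neither produced nor consumed: ",
                                   unstated))
  problems
}

#' Allocated burden of a process tree
#'
#' Propagates the raw-milk burden and the step energies to the BMS through
#' the tree. At every multi-output step the burden arriving at the step is
#' split over the outputs by [allocation_factors()] under the chosen basis;
#' shares compose multiplicatively along the tree. Step energy dedicated to a
#' stream is assigned entirely along that stream's path; shared step energy
#' is split by the same basis as the raw milk.
#'
#' @param tree a [dairy_mass_balance()] result (or any tree with the same
#'   structure, e.g. the toy trees used for verification).
#' @param basis allocation basis, see [allocation_factors()].
#' @return list with `raw_milk` (kg allocated to BMS), `electricity` and
#'   `heat` (MJ allocated to BMS), and `share` (fraction of the raw-milk
#'   burden carried by the BMS).
#' @export
allocated_burden <- function(tree, basis = "dry_mass") {
  basis <- match.arg(basis, ALLOCATION_BASES)
  problems <- check_process_tree(tree)
  if (length(problems)) stop("invalid process tree: ",
                             paste(problems, collapse = "; "))
  df <- tree$streams
  steps <- tree$steps
  step_consuming <- function(stream) {
    for (st in steps) if (stream %in% st$inputs) return(st)
    NULL
  }
  bfrac_env <- new.env()
  bfrac <- function(stream) {
    if (!is.null(bfrac_env[[stream]])) return(bfrac_env[[stream]])
    st <- step_consuming(stream)
    val <- if (is.null(st)) {
      as.numeric(df$destined_for_bms[df$name == stream])
    } else {
      step_share(st)
    }
    bfrac_env[[stream]] <- val
    val
  }
  step_share <- function(st) {
    outs <- df[df$name %in% st$outputs, , drop = FALSE]
    if (nrow(outs) == 1) return(bfrac(outs$name))
    fac <- allocation_factors(outs, basis)
    sum(fac * vapply(outs$name, bfrac, numeric(1)))
  }
  consumed <- unlist(lapply(steps, `[[`, "inputs"))
  produced <- unlist(lapply(steps, `[[`, "outputs"))
  root <- setdiff(consumed, produced)[1]  # the raw input stream
  raw_share <- bfrac(root)
  elec <- 0; heat <- 0
  for (st in steps) {
    share <- if (!is.na(st$dedicated_to)) bfrac(st$dedicated_to) else step_share(st)
    elec <- elec + st$electricity * share
    heat <- heat + st$heat * share
  }
  list(raw_milk = tree$raw_milk_input * raw_share,
       electricity = elec, heat = heat, share = raw_share)
}
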