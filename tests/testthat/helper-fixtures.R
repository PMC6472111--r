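# Shared fixtures: cached scenarios, a toy process tree, and an exhaustive
# path-enumeration oracle for allocation (independent of allocated_burden).

scenarios_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_scenarios()
    cache
  }
})

production_countries <- c("New Zealand", "United States", "Brazil", "France")
consumption_countries <- c("United Kingdom", "China", "Brazil", "Vietnam")

paired_production <- function(name) {
  s <- scenarios_cache()[[name]]
  scenarios_cache()[[s$consumption$production_country %||% name]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A three-step toy tree: root -> (A, mid1); mid1 -> (B, mid2);
# mid2 -> (bms_x, bms_y, C). Streams carry distinct properties so every
# allocation basis gives different factors.
toy_tree <- function() {
  streams <- rbind(
    co_product_stream("root", 10, 2.0, 0.5, 0.6, 30, 1.0),
    co_product_stream("A", 2, 0.5, 0.3, 0.1, 12, 4.0),
    co_product_stream("mid1", 8, 1.5, 0.2, 0.5, 18, 1.5),
    co_product_stream("B", 3, 0.6, 0.05, 0.3, 7, 5.0),
    co_product_stream("mid2", 5, 0.9, 0.15, 0.2, 11, 0.8),
    co_product_stream("bms_x", 1, 0.4, 0.1, 0.1, 6, 6.0,
                      destined_for_bms = TRUE),
    co_product_stream("bms_y", 1.5, 0.3, 0.02, 0.08, 3, 2.0,
                      destined_for_bms = TRUE),
    co_product_stream("C", 2.5, 0.2, 0.03, 0.02, 2, 0.3)
  )
  steps <- list(
    process_step("s1", "root", c("A", "mid1"), electricity = 2, heat = 5),
    process_step("s2", "mid1", c("B", "mid2"), electricity = 1, heat = 3),
    process_step("s3", "mid2", c("bms_x", "bms_y", "C"), electricity = 0.5,
                 heat = 1.5)
  )
  structure(list(streams = streams, steps = steps, raw_milk_input = 10,
                 waste_multiplier = 1, dairy_solids = 0.7),
            class = "bms_process_tree")
}

# Exhaustive path oracle: enumerate every root-to-terminal path, multiplying
# per-step fractions computed directly from stream properties.
oracle_property <- function(row, basis) {
  switch(basis,
         dry_mass = row$dry_mass,
         fat_protein = row$fat + row$protein,
         energy = row$energy,
         economic = row$price * row$dry_mass)
}

tree_root <- function(tree) {
  consumed <- unlist(lapply(tree$steps, `[[`, "inputs"))
  produced <- unlist(lapply(tree$steps, `[[`, "outputs"))
  setdiff(consumed, produced)[1]
}

oracle_paths <- function(tree, basis) {
  df <- tree$streams
  steps <- tree$steps
  paths <- list()
  walk <- function(stream, weight) {
    consumed <- FALSE
    for (st in steps) {
      if (stream %in% st$inputs) {
        consumed <- TRUE
        outs <- df[df$name %in% st$outputs, , drop = FALSE]
        props <- if (nrow(outs) == 1) 1 else
          vapply(seq_len(nrow(outs)), function(i)
            oracle_property(outs[i, ], basis), numeric(1))
        for (i in seq_len(nrow(outs)))
          walk(outs$name[i], weight * props[i] / sum(props))
      }
    }
    if (!consumed)
      paths[[length(paths) + 1]] <<- list(terminal = stream, weight = weight)
  }
  walk(tree_root(tree), 1)
  paths
}

oracle_allocated_share <- function(tree, basis) {
  df <- tree$streams
  paths <- oracle_paths(tree, basis)
  sum(vapply(paths, function(p)
    if (df$destined_for_bms[df$name == p$terminal]) p$weight else 0,
    numeric(1)))
}

# oracle for shared step energy: each step's energy times the summed weight
# of BMS-terminal paths leaving that step, enumerated independently
oracle_allocated_energy <- function(tree, basis, kind = "electricity") {
  df <- tree$streams
  total <- 0
  for (st in tree$steps) {
    sub <- structure(list(streams = df, steps = tree$steps,
                          raw_milk_input = tree$raw_milk_input,
                          waste_multiplier = 1),
                     class = "bms_process_tree")
    # share of this step's burden reaching BMS: restart enumeration at the
    # step's outputs
    outs <- df[df$name %in% st$outputs, , drop = FALSE]
    props <- vapply(seq_len(nrow(outs)), function(i)
      oracle_property(outs[i, ], basis), numeric(1))
    share <- 0
    for (i in seq_len(nrow(outs))) {
      w <- props[i] / sum(props)
      term_share <- terminal_share(sub, outs$name[i], basis)
      share <- share + w * term_share
    }
    total <- total + st[[kind]] * share
  }
  total
}

terminal_share <- function(tree, stream, basis) {
  df <- tree$streams
  for (st in tree$steps) {
    if (stream %in% st$inputs) {
      outs <- df[df$name %in% st$outputs, , drop = FALSE]
      props <- if (nrow(outs) == 1) 1 else
        vapply(seq_len(nrow(outs)), function(i)
          oracle_property(outs[i, ], basis), numeric(1))
      return(sum(vapply(seq_len(nrow(outs)), function(i)
        props[i] / sum(props) * terminal_share(tree, outs$name[i], basis),
        numeric(1))))
    }
  }
  as.numeric(df$destined_for_bms[df$name == stream])
}
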