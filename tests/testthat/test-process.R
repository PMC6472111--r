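# Dairy mass balance and co-product allocation.

test_that("allocation factors are property ratios summing to one", {
  s2 <- rbind(co_product_stream("a", 2, 1, 0.2, 0.3, 10, 2),
              co_product_stream("b", 2, 1, 0.1, 0.1, 5, 1))
  f <- allocation_factors(s2, "dry_mass")
  expect_equal(unname(f), c(0.5, 0.5))
  f_ec <- allocation_factors(s2, "economic")
  expect_equal(unname(f_ec), c(2 / 3, 1 / 3))
  for (basis in c("dry_mass", "fat_protein", "energy", "economic"))
    expect_equal(sum(allocation_factors(toy_tree()$streams[-1, ], basis)), 1)
})

test_that("a fat- and protein-free stream gets factor zero under fat_protein", {
  s2 <- rbind(co_product_stream("lactose", 1, 1, 0, 0, 17, 0.7),
              co_product_stream("wpc", 1, 1, 0.05, 0.8, 18, 7.5))
  f <- allocation_factors(s2, "fat_protein")
  expect_equal(unname(f[["lactose"]]), 0)
  expect_equal(unname(f[["wpc"]]), 1)
})

test_that("an all-zero basis property is an error", {
  s2 <- rbind(co_product_stream("a", 1, 1, 0, 0, 5, 0),
              co_product_stream("b", 1, 1, 0, 0, 5, 0))
  expect_error(allocation_factors(s2, "economic"), "undefined")
})

test_that("baseline mass balance reproduces the reference flows", {
  tree <- dairy_mass_balance(baseline_recipe())
  expect_equal(tree$raw_milk_input, 13.7, tolerance = 1e-6)
  b <- allocated_burden(tree, "dry_mass")
  expect_equal(format_sig(tree$raw_milk_input, 3), "13.7")
  expect_equal(format_sig(b$raw_milk, 2), "6.6")
  expect_length(check_issues <- bmslca:::check_process_tree(tree), 0)
})

test_that("zero-dairy recipe needs no raw milk and demands scale linearly", {
  oil_only <- recipe(c(vegetable_oil = 1))
  t0 <- dairy_mass_balance(oil_only)
  expect_equal(t0$raw_milk_input, 0)
  half <- recipe(c(skimmed_milk = 0.075, whey_protein_concentrate = 0.05,
                   lactose = 0.25, vegetable_oil = 0.625))
  th <- dairy_mass_balance(half)
  tb <- dairy_mass_balance(baseline_recipe())
  expect_equal(th$raw_milk_input * 2, tb$raw_milk_input, tolerance = 1e-9)
  for (nm in c("whey", "cream", "cheese_curd")) {
    expect_equal(2 * th$streams$dry_mass[th$streams$name == nm],
                 tb$streams$dry_mass[tb$streams$name == nm],
                 tolerance = 1e-9)
  }
})

test_that("infeasible compositions name the binding constraint", {
  proc <- process_config()
  proc$milk_composition$whey_protein_share <- 0
  expect_error(dairy_mass_balance(baseline_recipe(), proc), "whey_protein")
})

test_that("chain waste inflates the tree by the closed-form multiplier", {
  tb <- dairy_mass_balance(baseline_recipe())
  tw <- dairy_mass_balance(baseline_recipe(), chain_waste = c(0.1, 0.1))
  expect_equal(tw$raw_milk_input / tb$raw_milk_input, 1 / 0.81,
               tolerance = 1e-9)
})

test_that("allocated burden equals the exhaustive path oracle on a toy tree", {
  tree <- toy_tree()
  for (basis in c("dry_mass", "fat_protein", "energy", "economic")) {
    got <- allocated_burden(tree, basis)
    expect_equal(got$share, oracle_allocated_share(tree, basis),
                 tolerance = 1e-12, label = basis)
    expect_equal(got$electricity,
                 oracle_allocated_energy(tree, basis, "electricity"),
                 tolerance = 1e-12)
    expect_equal(got$heat, oracle_allocated_energy(tree, basis, "heat"),
                 tolerance = 1e-12)
  }
})

test_that("terminal allocation factors conserve the whole burden", {
  tree <- toy_tree()
  df <- tree$streams
  for (basis in c("dry_mass", "fat_protein", "energy", "economic")) {
    paths <- oracle_paths(tree, basis)
    expect_equal(sum(vapply(paths, `[[`, numeric(1), "weight")), 1,
                 tolerance = 1e-12)
  }
  # and on the real tree: BMS share plus co-product shares = 1
  real <- dairy_mass_balance(baseline_recipe())
  for (basis in c("dry_mass", "fat_protein", "energy", "economic")) {
    shares <- vapply(c("cream", "cheese_curd", "permeate", "bms"),
                     function(nm) terminal_share(real, nm, basis), numeric(1))
    # burden entering each terminal via the root
    total <- oracle_allocated_share(real, basis) +
      sum(vapply(oracle_paths(real, basis), function(p)
        if (p$terminal %in% c("cream", "cheese_curd", "permeate"))
          p$weight else 0, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-9, label = basis)
  }
})

test_that("allocated burden ordering: fat_protein < energy < dry_mass, economic < dry_mass", {
  tree <- dairy_mass_balance(baseline_recipe())
  sh <- vapply(c("dry_mass", "fat_protein", "energy", "economic"),
               function(b) allocated_burden(tree, b)$share, numeric(1))
  expect_lt(sh[["fat_protein"]], sh[["energy"]])
  expect_lt(sh[["energy"]], sh[["dry_mass"]])
  expect_lt(sh[["economic"]], sh[["dry_mass"]])
})

test_that("dedicated spray-dry energy is fully assigned to the BMS", {
  tree <- dairy_mass_balance(baseline_recipe())
  se <- process_config()$step_energy$wet_mix_spray_dry
  b <- allocated_burden(tree, "dry_mass")
  expect_gte(b$electricity, se$electricity)
  expect_gte(b$heat, se$heat)
})

test_that("stream invariants are enforced", {
  expect_error(co_product_stream("x", 1, 2), "dry_mass")
  expect_error(co_product_stream("x", 1, 1, fat = 0.8, protein = 0.4),
               "fat")
})

test_that("process trees serialise to YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_process_tree(dairy_mass_balance(baseline_recipe()), f)
  obj <- yaml::read_yaml(f)
  expect_equal(obj$raw_milk_input, 13.7, tolerance = 1e-6)
  expect_true(length(obj$streams) >= 10)
})
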