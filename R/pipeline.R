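# End-to-end pipeline runner and report generation: the three stages
# (production -> consumption -> breastfeeding comparison) for all configured
# countries, result tables in the shape of the reported tables, and the
# comparison figure series.

#' Run manifest
#'
#' Everything needed to re-run a pipeline bit-identically: the configuration
#' directory, seed, Monte Carlo size and switches.
#'
#' @param countries country names to run (default: all packaged).
#' @param seed integer seed.
#' @param n Monte Carlo draws.
#' @param basis allocation basis.
#' @param gwp GWP set label.
#' @param sterilisation_mode sterilisation mode.
#' @param include_luc include land-use change.
#' @param config_dir configuration directory (default: packaged).
#' @return list of class `bms_manifest`.
#' @export
run_manifest <- function(countries = NULL, seed = 1, n = 2000,
                         basis = "dry_mass", gwp = "AR4",
                         sterilisation_mode = "stovetop",
                         include_luc = FALSE, config_dir = NULL) {
  structure(list(countries = countries, seed = as.integer(seed),
                 n = as.integer(n), basis = basis, gwp = gwp,
                 sterilisation_mode = sterilisation_mode,
                 include_luc = include_luc, config_dir = config_dir,
                 version = as.character(utils::packageVersion("bmslca"))),
            class = "bms_manifest")
}

#' Run the full pipeline
#'
#' Executes production, consumption and breastfeeding-comparison stages for
#' every configured country and assembles the result tables. Re-running
#' with the same manifest reproduces the bundle exactly.
#'
#' @param manifest a [run_manifest()].
#' @return list of class `bms_bundle` with data.frames `production`,
#'   `consumption`, `diet`, `comparison` and the `manifest`.
#' @export
run_pipeline <- function(manifest = run_manifest()) {
  scens <- default_scenarios(manifest$config_dir)
  if (!is.null(manifest$countries)) {
    missing <- setdiff(manifest$countries, names(scens))
    if (length(missing))
      stop("unknown countries in manifest: ", paste(missing, collapse = ", "))
    scens <- scens[manifest$countries]
  }
  gwp <- gwp_set(manifest$gwp)
  basis <- manifest$basis
  feeding <- feeding_parameters()

  prods <- Filter(function(s) !is.null(s$production), scens)
  cons <- Filter(function(s) !is.null(s$consumption), scens)

  prod_rows <- list(); prod_results <- list()
  for (s in prods) {
    det <- cfp_production(s, basis = basis, gwp = gwp)
    mc <- monte_carlo(s, n = manifest$n, seed = manifest$seed,
                      mode = "production", basis = basis, gwp = gwp)
    sm <- mc$summary
    sd_of <- function(nm) sm$sd[sm$output == nm]
    v <- stages(det)
    prod_results[[s$country]] <- det
    prod_rows[[s$country]] <- data.frame(
      country = s$country,
      raw_milk = v[["raw_milk"]], raw_milk_sd = sd_of("raw_milk"),
      vegetable_oils = v[["vegetable_oils"]],
      vegetable_oils_sd = sd_of("vegetable_oils"),
      processing = v[["processing"]], processing_sd = sd_of("processing"),
      packaging = v[["packaging"]], transport = v[["transport"]],
      total = total_cfp(det), total_sd = sd_of("total"),
      stringsAsFactors = FALSE)
  }

  # paired production scenarios always come from the full packaged set
  all_scens <- default_scenarios(manifest$config_dir)
  cons_rows <- list(); comp_rows <- list(); diet_rows <- list()
  for (s in cons) {
    paired <- s$consumption$production_country %||% s$country
    ps <- all_scens[[paired]]
    det_p <- cfp_production(ps, basis = basis, gwp = gwp)
    det_c <- cfp_consumption(s, det_p, gwp = gwp,
                             sterilisation_mode = manifest$sterilisation_mode,
                             feeding = feeding)
    mc <- monte_carlo(s, n = manifest$n, seed = manifest$seed,
                      mode = "consumption", production_scenario = ps,
                      basis = basis, gwp = gwp,
                      sterilisation_mode = manifest$sterilisation_mode,
                      feeding = feeding)
    sm <- mc$summary
    sd_of <- function(nm) sm$sd[sm$output == nm]
    v <- stages(det_c)
    cons_rows[[s$country]] <- data.frame(
      country = s$country, production_country = paired,
      bms_production = v[["bms_production"]],
      bms_production_sd = sd_of("bms_production"),
      sterilisation = v[["sterilisation"]],
      sterilisation_sd = sd_of("sterilisation"),
      preparation = v[["preparation"]], preparation_sd = sd_of("preparation"),
      transport = v[["transport"]],
      bottle_production = v[["bottle_production"]],
      total = total_cfp(det_c), total_sd = sd_of("total"),
      stringsAsFactors = FALSE)

    bf <- cfp_breastfeeding(s, gwp = gwp,
                            include_luc = manifest$include_luc,
                            feeding = feeding)
    cmp_mc <- monte_carlo(s, n = manifest$n, seed = manifest$seed,
                          mode = "comparison", production_scenario = ps,
                          basis = basis, gwp = gwp,
                          sterilisation_mode = manifest$sterilisation_mode,
                          include_luc = manifest$include_luc,
                          feeding = feeding)
    smc <- cmp_mc$summary
    diet_rows[[s$country]] <- data.frame(
      country = s$country, plant = bf$plant, animal = bf$animal,
      cooking = bf$cooking, total_per_mj = bf$total,
      per_kg_bms = bf$per_kg_bms,
      per_kg_bms_sd = smc$sd[smc$output == "cfp_bf"],
      stringsAsFactors = FALSE)
    cmp <- compare_footprints(det_c, bf)
    comp_rows[[s$country]] <- data.frame(
      country = s$country, cfp_cons = cmp$cfp_cons, cfp_bf = cmp$cfp_bf,
      difference = cmp$difference, ratio = cmp$ratio,
      difference_sd = smc$sd[smc$output == "difference"],
      exceedance_probability = cmp_mc$exceedance_probability,
      stringsAsFactors = FALSE)
  }

  bind_rows <- function(rows) {
    if (!length(rows)) return(NULL)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  structure(list(production = bind_rows(prod_rows),
                 consumption = bind_rows(cons_rows),
                 diet = bind_rows(diet_rows),
                 comparison = bind_rows(comp_rows),
                 manifest = manifest),
            class = "bms_bundle")
}

empty_df <- function(cols) {
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                      cols))
  df
}

format_pm <- function(value, sd = NULL) {
  v <- format_sig(value)
  if (is.null(sd) || all(is.na(sd))) return(v)
  paste0(v, " ± ", format_sig(sd))
}

#' Render a result bundle to files
#'
#' Writes each table as a full-precision CSV (round-trippable) and as a
#' human-readable text table formatted to two significant figures with
#' plus/minus SD columns.
#'
#' @param bundle a [run_pipeline()] bundle.
#' @param dir output directory (created if needed).
#' @param style `"both"`, `"csv"` or `"text"`.
#' @return character vector of files written, invisibly.
#' @export
render_tables <- function(bundle, dir, style = c("both", "csv", "text")) {
  style <- match.arg(style)
  need <- c("production", "consumption", "diet", "comparison", "manifest")
  miss <- setdiff(need, names(bundle))
  if (length(miss)) stop("incomplete bundle, missing: ",
                         paste(miss, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in c("production", "consumption", "diet", "comparison")) {
    df <- bundle[[nm]]
    if (is.null(df)) df <- empty_df("country")
    if (style %in% c("both", "csv")) {
      f <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(df, f, row.names = FALSE)
      files <- c(files, f)
    }
    if (style %in% c("both", "text")) {
      f <- file.path(dir, paste0(nm, ".txt"))
      txt <- df
      for (col in names(txt)) {
        sd_col <- paste0(col, "_sd")
        if (is.numeric(txt[[col]]) && !endsWith(col, "_sd")) {
          txt[[col]] <- if (sd_col %in% names(df))
            format_pm(df[[col]], df[[sd_col]]) else format_sig(df[[col]])
        }
      }
      txt <- txt[, !endsWith(names(txt), "_sd"), drop = FALSE]
      writeLines(c(paste(names(txt), collapse = "\t"),
                   apply(txt, 1, paste, collapse = "\t")), f)
      files <- c(files, f)
    }
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(bundle$manifest), mf, auto_unbox = TRUE,
                       null = "null", digits = NA)
  files <- c(files, mf)
  invisible(files)
}

#' Comparison figure series
#'
#' Builds the plotted data series of the comparison figures: per-country
#' differences CFP_Cons - CFP_BF with 95% intervals under the default and
#' fat-and-protein allocation, each with and without bottle sterilisation
#' (the difference figure), and the ratio CFP_BF / CFP_Cons over a grid of
#' BMS waste fractions for both allocation bases (the waste-sweep figure).
#'
#' @param bundle a [run_pipeline()] bundle (used for its manifest; the
#'   series are recomputed deterministically).
#' @param waste_grid grid of BMS waste fractions.
#' @return list with data.frames `difference` and `waste_sweep`.
#' @export
figure_series <- function(bundle, waste_grid = seq(0, 0.5, by = 0.05)) {
  manifest <- bundle$manifest
  scens <- default_scenarios(manifest$config_dir)
  cons <- Filter(function(s) !is.null(s$consumption), scens)
  if (!is.null(manifest$countries))
    cons <- cons[intersect(names(cons), manifest$countries)]
  if (!is.null(bundle$comparison))
    cons <- cons[intersect(names(cons), bundle$comparison$country)]
  else cons <- list()
  gwp <- gwp_set(manifest$gwp)
  feeding <- feeding_parameters()
  diff_rows <- list(); sweep_rows <- list()
  all_scens <- default_scenarios(manifest$config_dir)
  for (s in cons) {
    paired <- s$consumption$production_country %||% s$country
    ps <- all_scens[[paired]]
    for (basis in c("dry_mass", "fat_protein")) {
      for (ster in c("stovetop", "none")) {
        mc <- monte_carlo(s, n = manifest$n, seed = manifest$seed,
                          mode = "comparison", production_scenario = ps,
                          basis = basis, gwp = gwp,
                          sterilisation_mode = ster, feeding = feeding)
        sm <- mc$summary
        d <- sm[sm$output == "difference", ]
        diff_rows[[length(diff_rows) + 1]] <- data.frame(
          country = s$country, basis = basis, sterilisation = ster,
          difference = d$point, ci95_low = d$ci95_low,
          ci95_high = d$ci95_high,
          exceedance_probability = mc$exceedance_probability,
          stringsAsFactors = FALSE)
      }
      det_p <- cfp_production(ps, basis = basis, gwp = gwp)
      sw <- waste_sweep(s, det_p, waste_grid, gwp = gwp, feeding = feeding)
      sw$country <- s$country
      sw$basis <- basis
      sweep_rows[[length(sweep_rows) + 1]] <- sw
    }
  }
  list(difference = do.call(rbind, diff_rows),
       waste_sweep = do.call(rbind, sweep_rows))
}

#' Plot the comparison figures
#'
#' Renders [figure_series()] data with ggplot2 (if installed) and writes the
#' underlying data as CSV; plots are always generated from the emitted data
#' files.
#'
#' @param series a [figure_series()] result.
#' @param dir output directory.
#' @return files written, invisibly.
#' @export
plot_figures <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "difference_series.csv")
  f2 <- file.path(dir, "waste_sweep_series.csv")
  utils::write.csv(series$difference, f1, row.names = FALSE)
  utils::write.csv(series$waste_sweep, f2, row.names = FALSE)
  files <- c(f1, f2)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    dd <- utils::read.csv(f1)
    dd$case <- paste(dd$basis, dd$sterilisation, sep = " / ")
    g1 <- ggplot2::ggplot(dd, ggplot2::aes(x = country, y = difference,
                                           colour = case)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = ci95_low,
                                            ymax = ci95_high),
                               position = ggplot2::position_dodge(0.5)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(y = "CFP_Cons - CFP_BF (kg CO2e per kg BMS)", x = NULL)
    p1 <- file.path(dir, "difference.pdf")
    ggplot2::ggsave(p1, g1, width = 7, height = 4)
    ds <- utils::read.csv(f2)
    g2 <- ggplot2::ggplot(ds, ggplot2::aes(x = waste, y = ratio,
                                           colour = country,
                                           linetype = basis)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 1, linetype = 3) +
      ggplot2::labs(x = "BMS waste fraction", y = "CFP_BF / CFP_Cons")
    p2 <- file.path(dir, "waste_sweep.pdf")
    ggplot2::ggsave(p2, g2, width = 7, height = 4)
    files <- c(files, p1, p2)
  }
  invisible(files)
}
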