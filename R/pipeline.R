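#' Pipeline stage: simulate a species batch to disk
#'
#' Writes, per species: the occurrence sample and validation set as CSV, and
#' the truth surface, covariate layers and reporting layer as ESRI ASCII
#' grids. A JSON run manifest records the resolved configuration, the
#' per-species derived seeds and stage completion, making later stages and
#' re-runs reproducible. Completed species are skipped unless `force`.
#'
#' @param outdir Output directory (created if missing).
#' @param n_species Number of species.
#' @param config An [sdm_config()].
#' @param master_seed Master seed (per-species seeds derived from it).
#' @param bias_mode `"biological"`, `"random"`, or `"alternate"`
#'   (odd species biological, even random).
#' @param force Recompute species whose outputs already exist?
#' @return The manifest (invisibly).
#' @export
run_simulate <- function(outdir, n_species, config = sdm_config(),
                         master_seed = 1, bias_mode = "alternate",
                         force = FALSE) {
  stopifnot(inherits(config, "sdm_config"))
  if (n_species < 1) stop("`n_species` must be >= 1", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  modes <- if (identical(bias_mode, "alternate")) {
    rep_len(c("biological", "random"), n_species)
  } else {
    rep_len(match.arg(bias_mode, c("biological", "random")), n_species)
  }
  manifest <- read_manifest(outdir)
  manifest$config <- config_manifest(config)
  manifest$master_seed <- master_seed
  manifest$version <- as.character(utils::packageVersion("sdmbench"))
  species <- purrr::map(seq_len(n_species), function(i) {
    id <- sprintf("sp%04d", i)
    seed_i <- derive_seed(master_seed, i, salt = 101L)
    paths <- species_paths(outdir, id, config$n_cov)
    done <- all(file.exists(unlist(paths)))
    if (!done || force) {
      sp <- simulate_species(id, modes[i], config, seed_i)
      readr::write_csv(
        tibble::tibble(x = sp$sample$x, y = sp$sample$y,
                       species_id = id, bias_mode = sp$bias_mode,
                       c = sp$clumping$c),
        paths$sample)
      readr::write_csv(sp$validation[, c("x", "y", "label")],
                       paths$validation)
      write_ascii_grid(sp$truth$p_noisy, config$grid, paths$truth)
      write_ascii_grid(sp$truth$p_clean, config$grid, paths$truth_clean)
      for (k in seq_len(config$n_cov)) {
        write_ascii_grid(sp$covariates$values[, k], config$grid,
                         paths$covariates[k])
      }
      write_ascii_grid(sp$reporting$rate, config$grid, paths$reporting)
    }
    list(species_id = id, rng_seed = seed_i, bias_mode = modes[i],
         simulated = TRUE)
  })
  manifest$species <- species
  manifest$stages$simulate <- list(completed = TRUE,
                                   n_species = n_species,
                                   time = format(Sys.time()))
  write_manifest(outdir, manifest)
  invisible(manifest)
}

species_paths <- function(outdir, id, n_cov = 5) {
  list(
    sample = file.path(outdir, paste0("sample_", id, ".csv")),
    validation = file.path(outdir, paste0("validation_", id, ".csv")),
    truth = file.path(outdir, paste0("truth_noisy_", id, ".asc")),
    truth_clean = file.path(outdir, paste0("truth_clean_", id, ".asc")),
    covariates = file.path(outdir,
                           paste0("cov", seq_len(n_cov), "_", id, ".asc")),
    reporting = file.path(outdir, paste0("reporting_", id, ".asc"))
  )
}

config_manifest <- function(config) {
  list(n_cols = config$grid$n_cols, n_rows = config$grid$n_rows,
       n_cov = config$n_cov, coef_sd = config$coef_sd,
       noise_sd = config$noise_sd, n_validation = config$n_validation,
       prevalence_bounds = config$prevalence_bounds,
       min_seeds = config$min_seeds, max_seeds = config$max_seeds,
       clump_range = config$clump_range,
       n_sample_range = config$n_sample_range,
       background_strategy = config$background_strategy,
       n_background = config$n_background,
       thin_distance = config$thin_distance,
       mesh_cutoff = config$gmrf$mesh_cutoff,
       prior_sd_beta = config$gmrf$prior_sd_beta,
       brt = unclass(config$brt),
       maxent = list(classes = config$maxent$classes,
                     beta = config$maxent$beta,
                     n_knots = config$maxent$n_knots),
       methods = config$methods)
}

read_manifest <- function(outdir) {
  p <- file.path(outdir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = FALSE)
  else list(stages = list())
}

write_manifest <- function(outdir, manifest) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# Rebuild an sdm_species object from the on-disk artifacts of run_simulate.
load_species <- function(outdir, id, manifest_entry, config) {
  paths <- species_paths(outdir, id, config$n_cov)
  missing <- !file.exists(c(paths$sample, paths$validation, paths$truth,
                            paths$covariates[seq_len(config$n_cov)]))
  if (any(missing)) {
    stop("missing simulate-stage artifacts for ", id,
         "; run run_simulate() first", call. = FALSE)
  }
  vals <- vapply(seq_len(config$n_cov), function(k) {
    read_ascii_grid(paths$covariates[k])$values
  }, numeric(n_cells(config$grid)))
  colnames(vals) <- paste0("cov", seq_len(config$n_cov))
  covariates <- structure(
    list(grid = config$grid, values = vals, layer_meta = NULL),
    class = "covariate_stack")
  truth <- structure(
    list(grid = config$grid,
         p_clean = read_ascii_grid(paths$truth_clean)$values,
         p_noisy = read_ascii_grid(paths$truth)$values,
         noise_sd = config$noise_sd, species_model = NULL),
    class = "truth_surface")
  sample_df <- readr::read_csv(paths$sample, show_col_types = FALSE)
  validation <- readr::read_csv(paths$validation, show_col_types = FALSE)
  validation$cell <- point_to_cell(config$grid, validation$x, validation$y)
  attr(validation, "prevalence") <- mean(validation$label)
  structure(
    list(covariates = covariates, truth = truth, validation = validation,
         sample = sample_df[, c("x", "y")],
         clumping = clumping_params(sample_df$c[1]),
         bias_mode = sample_df$bias_mode[1], species_id = id,
         rng_seed = manifest_entry$rng_seed, n_redraws = NA),
    class = "sdm_species")
}

load_batch <- function(outdir, config) {
  manifest <- read_manifest(outdir)
  if (is.null(manifest$species)) {
    stop("no simulate-stage manifest in ", outdir, call. = FALSE)
  }
  structure(
    purrr::map(manifest$species, function(e) {
      load_species(outdir, e$species_id, e, config)
    }),
    class = "sdm_batch")
}

#' Pipeline stage: fit engines and evaluate AUC from disk artifacts
#'
#' Loads the simulated species from `outdir`, fits the requested engines,
#' writes per-species result files (the resume unit), then the combined AUC
#' table, diagnostics/scenario table, scenario summaries and method
#' ranking.
#'
#' @param outdir Directory holding [run_simulate()] outputs.
#' @param config The same [sdm_config()] used to simulate.
#' @param methods Engines to fit (default from config).
#' @param force Refit species whose result files exist?
#' @return List with `results`, `diagnostics`, `summary`, `ranking`
#'   (invisibly); CSVs written alongside the inputs.
#' @export
run_fit_evaluate <- function(outdir, config = sdm_config(),
                             methods = config$methods, force = FALSE) {
  batch <- load_batch(outdir, config)
  results <- purrr::map_dfr(batch, function(sp) {
    rp <- file.path(outdir,
                    paste0("results_", sp$species_id, ".csv"))
    if (file.exists(rp) && !force) {
      res <- readr::read_csv(rp, show_col_types = FALSE)
      if (setequal(res$method, methods)) return(res)
    }
    fits <- fit_species_models(sp, config, methods)
    res <- evaluate_species(fits, sp$validation, species_id = sp$species_id)
    readr::write_csv(res, rp)
    res
  })
  readr::write_csv(results, file.path(outdir, "auc_results.csv"))
  if (length(batch) >= 4) {
    diagnostics <- diagnose_batch(batch)
    summary <- summarize_by_scenario(results, diagnostics)
    ranking <- rank_methods(summary)
    readr::write_csv(diagnostics, file.path(outdir, "diagnostics.csv"))
    readr::write_csv(summary, file.path(outdir, "scenario_summary.csv"))
    readr::write_csv(ranking$top2_counts,
                     file.path(outdir, "method_ranking.csv"))
  } else {
    message("fewer than 4 species: skipping scenario binning and ranking")
    diagnostics <- NULL
    summary <- NULL
    ranking <- NULL
  }
  manifest <- read_manifest(outdir)
  manifest$stages$fit_evaluate <- list(completed = TRUE,
                                       methods = methods,
                                       time = format(Sys.time()))
  write_manifest(outdir, manifest)
  invisible(list(results = results, diagnostics = diagnostics,
                 summary = summary, ranking = ranking))
}

#' Pipeline stage: run a configuration sweep from disk artifacts
#'
#' @param outdir Directory holding [run_simulate()] outputs.
#' @param axis Sweep axis name (see [sweep_grid()]).
#' @param config Base [sdm_config()].
#' @param levels Optional custom ladder.
#' @return The sweep results tibble (invisibly); written as
#'   `sweep_<axis>.csv`.
#' @export
run_config_sweep <- function(outdir, axis, config = sdm_config(),
                             levels = NULL) {
  batch <- load_batch(outdir, config)
  res <- run_sweep(batch, sweep_grid(axis, levels), config)
  readr::write_csv(res, file.path(outdir, paste0("sweep_", axis, ".csv")))
  manifest <- read_manifest(outdir)
  manifest$stages[[paste0("sweep_", axis)]] <-
    list(completed = TRUE, time = format(Sys.time()))
  write_manifest(outdir, manifest)
  invisible(res)
}
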