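#' Simulate one virtual species with its biased occurrence sample
#'
#' Runs the full generative chain for a single species: covariate stack,
#' random generating regression, noisy truth surface, validation points,
#' reporting layer, seed points, and the clumped presence-only sample.
#' Species whose validation prevalence falls outside the configured bounds
#' (AUC would be unstable with a nearly one-class validation set), or whose
#' truth is effectively unsampleable under biological bias, are rejected and
#' redrawn with a fresh derived seed.
#'
#' @param species_id Identifier recorded in outputs.
#' @param bias_mode `"biological"` or `"random"`.
#' @param config An [sdm_config()].
#' @param rng_seed Integer seed for this species.
#' @return A list of class `sdm_species` with elements `covariates`,
#'   `truth`, `validation`, `reporting`, `seeds`, `sample`, `clumping`,
#'   `bias_mode`, `species_id`, `rng_seed`, `n_redraws`.
#' @export
simulate_species <- function(species_id, bias_mode, config, rng_seed) {
  stopifnot(inherits(config, "sdm_config"))
  bias_mode <- match.arg(bias_mode, c("biological", "random"))
  pool <- enumerate_term_pool(config$n_cov)
  for (redraw in 0:config$max_species_redraws) {
    sd_i <- derive_seed(rng_seed, redraw)
    covariates <- generate_covariates(config$grid, config$n_cov,
                                      derive_seed(sd_i, 1))
    model <- draw_species_model(pool, derive_seed(sd_i, 2), config$coef_sd)
    truth <- predict_truth_surface(model, covariates, config$noise_sd,
                                   derive_seed(sd_i, 3))
    validation <- sample_validation_points(truth, config$n_validation,
                                           derive_seed(sd_i, 4),
                                           label_rule = config$label_rule)
    prev <- attr(validation, "prevalence")
    if (prev < config$prevalence_bounds[1] ||
        prev > config$prevalence_bounds[2]) next
    reporting <- generate_reporting_layer(config$grid, derive_seed(sd_i, 5))
    seeds <- draw_seed_points(config$grid, derive_seed(sd_i, 6),
                              config$min_seeds, config$max_seeds)
    seeds <- filter_seeds(seeds, reporting, derive_seed(sd_i, 7))
    clump <- clumping_params(withr::with_seed(derive_seed(sd_i, 8),
      stats::runif(1, config$clump_range[1], config$clump_range[2])))
    n_total <- withr::with_seed(derive_seed(sd_i, 9),
      config$n_sample_range[1] +
        sample.int(config$n_sample_range[2] -
                     config$n_sample_range[1] + 1L, 1L) - 1L)
    sample <- tryCatch(
      draw_clumped_samples(seeds, clump, truth, bias_mode, n_total,
                           derive_seed(sd_i, 10)),
      error = function(e) NULL)
    if (is.null(sample)) next
    return(structure(
      list(covariates = covariates, truth = truth, validation = validation,
           reporting = reporting, seeds = seeds, sample = sample,
           clumping = clump, bias_mode = bias_mode,
           species_id = species_id, rng_seed = rng_seed,
           n_redraws = redraw),
      class = "sdm_species"))
  }
  stop(sprintf(
    "species %s: no acceptable draw in %d attempts (prevalence bounds %s)",
    species_id, config$max_species_redraws + 1,
    paste(config$prevalence_bounds, collapse = "-")), call. = FALSE)
}

#' @export
print.sdm_species <- function(x, ...) {
  cat(sprintf(
    "<sdm_species> %s: %d samples (%s bias, c = %.1f), prevalence %.3f\n",
    x$species_id, nrow(x$sample), x$bias_mode, x$clumping$c,
    attr(x$validation, "prevalence")))
  invisible(x)
}

#' Simulate a batch of virtual species
#'
#' @param n_species Number of species.
#' @param bias_mode Single mode recycled, or a length-`n_species` vector
#'   mixing `"biological"` and `"random"`.
#' @param config An [sdm_config()].
#' @param master_seed Master seed; per-species seeds are derived from it so
#'   the batch is extensible without disturbing earlier species.
#' @return A list of `sdm_species`, class `sdm_batch`.
#' @export
simulate_species_batch <- function(n_species, bias_mode = "biological",
                                   config = sdm_config(), master_seed = 1) {
  if (n_species < 1) stop("`n_species` must be >= 1", call. = FALSE)
  bias_mode <- rep_len(bias_mode, n_species)
  out <- purrr::map(seq_len(n_species), function(i) {
    simulate_species(sprintf("sp%04d", i), bias_mode[i], config,
                     derive_seed(master_seed, i, salt = 101L))
  })
  structure(out, class = "sdm_batch")
}

#' @export
print.sdm_batch <- function(x, ...) {
  cat(sprintf("<sdm_batch> %d species (%s)\n", length(x),
              paste(names(table(purrr::map_chr(x, "bias_mode"))),
                    table(purrr::map_chr(x, "bias_mode")),
                    collapse = ", ")))
  invisible(x)
}

#' Diagnostics table for a simulated batch
#'
#' Computes Clark-Evans clumping and convex-hull coverage per species and
#' assigns scenario bins by the batch median splits.
#'
#' @param batch An [simulate_species_batch()] result.
#' @return A tibble with one row per species: `species_id`, `bias_mode`,
#'   `n_points`, `clark_evans`, `coverage`, `clump_bin`, `coverage_bin`,
#'   `scenario`.
#' @export
diagnose_batch <- function(batch) {
  d <- purrr::map_dfr(batch, function(sp) {
    dplyr::bind_cols(
      tibble::tibble(species_id = sp$species_id, bias_mode = sp$bias_mode),
      sample_diagnostics(sp$sample, sp$validation, sp$covariates$grid)
    )
  })
  assign_scenarios(d)
}
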