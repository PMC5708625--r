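#' Assemble a validated run configuration
#'
#' Bundles every tunable of the simulate-sample-fit-evaluate pipeline with
#' the study defaults: a 1-degree grid, 5 covariates, logit-scale truth
#' noise 0.25, 1000 validation points, 5-20 uniform seed points filtered
#' through a 6-region reporting layer, clumping coefficient uniform on
#' [1, 50], sample sizes uniform on [25, 500], 1000 random background
#' points, and the four engines at their defaults.
#'
#' @param n_cols,n_rows Grid size (default 90 x 45; the full 1-degree world
#'   is 360 x 180).
#' @param n_cov Number of covariate layers.
#' @param coef_sd Coefficient scale of the generating regression.
#' @param noise_sd Logit-scale truth noise.
#' @param n_validation Validation points per species.
#' @param label_rule Validation labelling rule: `"threshold"` (realised
#'   occupancy, default) or `"bernoulli"` (see
#'   [sample_validation_points()]).
#' @param prevalence_bounds Accept a species only if validation prevalence
#'   falls inside this interval.
#' @param min_seeds,max_seeds Seed-point count bounds.
#' @param clump_range Clumping-coefficient range (cells).
#' @param n_sample_range Occurrence sample-size range.
#' @param background_strategy One of `"R"`, `"SW"`, `"ST"`, `"B"`.
#' @param n_background Background points per species.
#' @param thin_distance Presence-thinning distance for `ST`/`B`.
#' @param design [design_spec()] for the Bayesian GLM engines.
#' @param gmrf [gmrf_spec()] for the spatial engine.
#' @param brt [brt_settings()] for the boosted-tree engine.
#' @param maxent [maxent_feature_spec()] for the MaxEnt-style engine.
#' @param methods Engines to fit.
#' @param max_species_redraws How many times a degenerate species (one-class
#'   validation or unsampleable truth) may be redrawn.
#' @return A list of class `sdm_config`.
#' @export
sdm_config <- function(n_cols = 90, n_rows = 45, n_cov = 5,
                       coef_sd = 1, noise_sd = 0.25,
                       n_validation = 1000,
                       label_rule = c("threshold", "bernoulli"),
                       prevalence_bounds = c(0.05, 0.95),
                       min_seeds = 5, max_seeds = 20,
                       clump_range = c(1, 50),
                       n_sample_range = c(25, 500),
                       background_strategy = "R",
                       n_background = 1000,
                       thin_distance = 2,
                       design = design_spec(covariate_subset = seq_len(n_cov)),
                       gmrf = gmrf_spec(),
                       brt = brt_settings(),
                       maxent = maxent_feature_spec(),
                       methods = c("spatial_bayes_glm",
                                   "nonspatial_bayes_glm",
                                   "brt", "maxent_like"),
                       max_species_redraws = 50) {
  cfg <- list(
    grid = grid_spec(n_cols, n_rows),
    n_cov = as.integer(n_cov), coef_sd = coef_sd, noise_sd = noise_sd,
    n_validation = as.integer(n_validation),
    label_rule = match.arg(label_rule),
    prevalence_bounds = prevalence_bounds,
    min_seeds = min_seeds, max_seeds = max_seeds,
    clump_range = clump_range, n_sample_range = as.integer(n_sample_range),
    background_strategy = match.arg(background_strategy,
                                    c("R", "SW", "ST", "B")),
    n_background = as.integer(n_background),
    thin_distance = thin_distance,
    design = design, gmrf = gmrf, brt = brt, maxent = maxent,
    methods = match.arg(methods, c("spatial_bayes_glm",
                                   "nonspatial_bayes_glm",
                                   "brt", "maxent_like"),
                        several.ok = TRUE),
    max_species_redraws = as.integer(max_species_redraws)
  )
  stopifnot(cfg$noise_sd >= 0, cfg$coef_sd > 0,
            cfg$n_validation >= 2,
            cfg$prevalence_bounds[1] < cfg$prevalence_bounds[2],
            cfg$clump_range[1] >= 1, cfg$clump_range[2] <= 50,
            cfg$n_sample_range[1] >= 25, cfg$n_sample_range[2] <= 500)
  structure(cfg, class = "sdm_config")
}

#' @export
print.sdm_config <- function(x, ...) {
  cat(sprintf(
    "<sdm_config> grid %dx%d, %d covariates, methods: %s\n",
    x$grid$n_cols, x$grid$n_rows, x$n_cov,
    paste(x$methods, collapse = ", ")))
  invisible(x)
}

# Deterministic 31-bit seed derivation (two Lehmer multiplications around an
# additive mix) so per-species streams are independent of batch size and
# extension order.
derive_seed <- function(master, index, salt = 0L) {
  x <- as.numeric(master) %% 2147483647
  x <- (x * 16807) %% 2147483647
  x <- (x + as.numeric(index) * 2654435761 +
          as.numeric(salt) * 97531) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x) + 1L
}
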