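#' Fit the configured SDM engines for one simulated species
#'
#' Applies the configured background strategy (thinning presences for
#' `ST`/`B`, spatially weighted background for `SW`/`B`), builds the
#' per-engine designs (linear + optional squares/interactions for the
#' Bayesian GLMs, linear covariates for the trees, raw covariates expanded
#' internally by the MaxEnt-style engine) and fits every requested engine.
#'
#' @param species An [simulate_species()] result.
#' @param config An [sdm_config()].
#' @param methods Engines to fit (default `config$methods`).
#' @return Named list of `fitted_sdm` objects.
#' @export
fit_species_models <- function(species, config, methods = config$methods) {
  stopifnot(inherits(species, "sdm_species"),
            inherits(config, "sdm_config"))
  covs <- species$covariates
  presences <- species$sample
  strategy <- config$background_strategy
  if (strategy %in% c("ST", "B")) {
    presences <- thin_presences(presences, config$thin_distance)
  }
  background <- generate_background(
    covs$grid, presences, strategy, config$n_background,
    derive_seed(species$rng_seed, 1, salt = 211L))
  pts <- dplyr::bind_rows(presences[, c("x", "y")],
                          background[, c("x", "y")])
  y <- c(rep(1, nrow(presences)), rep(0, nrow(background)))

  fits <- list()
  if ("nonspatial_bayes_glm" %in% methods ||
      "spatial_bayes_glm" %in% methods) {
    glm_design <- build_design(covs, pts, config$design)
    if ("nonspatial_bayes_glm" %in% methods) {
      fits$nonspatial_bayes_glm <- fit_nonspatial_bayes_glm(
        y, glm_design, covs, prior_sd_beta = config$gmrf$prior_sd_beta)
    }
    if ("spatial_bayes_glm" %in% methods) {
      fits$spatial_bayes_glm <- fit_spatial_bayes_glm(
        y, glm_design, covs, pts, spec = config$gmrf)
    }
  }
  if ("brt" %in% methods) {
    brt_design <- build_design(
      covs, pts,
      design_spec(config$design$covariate_subset,
                  include_squares = FALSE, include_interactions = FALSE))
    fits$brt <- fit_brt(y, brt_design, covs, config$brt,
                        derive_seed(species$rng_seed, 2, salt = 211L))
  }
  if ("maxent_like" %in% methods) {
    fits$maxent_like <- fit_maxent_like(
      presences, background, covs, spec = config$maxent,
      covariate_subset = config$design$covariate_subset)
  }
  fits[intersect(c("spatial_bayes_glm", "nonspatial_bayes_glm",
                   "brt", "maxent_like"), names(fits))]
}

#' Fit and score a whole batch
#'
#' @param batch An [simulate_species_batch()] result.
#' @param config An [sdm_config()].
#' @param methods Engines to fit.
#' @param config_id Label recorded with every result row.
#' @return Tibble of per-species AUCs: `species_id`, `method`, `config_id`,
#'   `auc`.
#' @export
evaluate_batch <- function(batch, config = sdm_config(),
                           methods = config$methods,
                           config_id = "default") {
  purrr::map_dfr(batch, function(sp) {
    fits <- fit_species_models(sp, config, methods)
    res <- evaluate_species(fits, sp$validation, species_id = sp$species_id)
    res$config_id <- config_id
    res
  })
}
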