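#' Define a configuration sweep axis
#'
#' Supported axes and their default ladders mirror the conventional
#' brute-force configuration comparison: background strategies
#' `{R, SW, ST, B}`; covariate-subset sizes; interaction terms on/off;
#' MaxEnt beta ladder and feature-class sets; the four BRT knobs; and the
#' spatial mesh cut-off from 0.5 to 8 degrees.
#'
#' @param axis One of `"background_strategy"`, `"covariate_reduction"`,
#'   `"interactions"`, `"maxent_beta"`, `"maxent_features"`,
#'   `"brt_learning_rate"`, `"brt_tree_complexity"`, `"brt_bag_fraction"`,
#'   `"brt_n_trees"`, `"mesh_cutoff"`.
#' @param levels Ordered list/vector of >= 2 levels; `NULL` uses the default
#'   ladder for the axis.
#' @return A list of class `sweep_grid`.
#' @export
sweep_grid <- function(axis, levels = NULL) {
  axis <- match.arg(axis, c("background_strategy", "covariate_reduction",
                            "interactions", "maxent_beta",
                            "maxent_features", "brt_learning_rate",
                            "brt_tree_complexity", "brt_bag_fraction",
                            "brt_n_trees", "mesh_cutoff"))
  if (is.null(levels)) {
    levels <- switch(axis,
      background_strategy = c("R", "SW", "ST", "B"),
      covariate_reduction = c(5, 4, 3, 2),
      interactions = c(FALSE, TRUE),
      maxent_beta = c(0.5, 1, 2, 4),
      maxent_features = list("L", c("L", "Q"), c("L", "Q", "H"),
                             c("L", "Q", "H", "P", "T"), "AF"),
      brt_learning_rate = c(0.001, 0.01, 0.1),
      brt_tree_complexity = c(1, 3, 5),
      brt_bag_fraction = c(0.5, 0.75, 1),
      brt_n_trees = c(250, 1000, 4000),
      mesh_cutoff = c(0.5, 1, 2, 4, 8)
    )
  }
  if (length(levels) < 2) stop("a sweep needs >= 2 levels", call. = FALSE)
  structure(list(axis = axis, levels = levels), class = "sweep_grid")
}

# Engines whose fit changes along the axis; only these are refitted.
sweep_methods <- function(axis, methods) {
  affected <- switch(axis,
    background_strategy = ,
    covariate_reduction = methods,
    interactions = c("spatial_bayes_glm", "nonspatial_bayes_glm"),
    maxent_beta = ,
    maxent_features = "maxent_like",
    brt_learning_rate = ,
    brt_tree_complexity = ,
    brt_bag_fraction = ,
    brt_n_trees = "brt",
    mesh_cutoff = "spatial_bayes_glm"
  )
  intersect(methods, affected)
}

# Return base_config modified to one sweep level.
apply_sweep_level <- function(config, axis, level) {
  switch(axis,
    background_strategy = {
      config$background_strategy <- level
    },
    covariate_reduction = {
      config$design <- design_spec(
        seq_len(level),
        include_squares = config$design$include_squares,
        include_interactions = config$design$include_interactions)
    },
    interactions = {
      config$design <- design_spec(
        config$design$covariate_subset,
        include_squares = config$design$include_squares,
        include_interactions = level)
    },
    maxent_beta = {
      config$maxent <- maxent_feature_spec(
        config$maxent$classes, beta = level,
        n_knots = config$maxent$n_knots)
    },
    maxent_features = {
      config$maxent <- maxent_feature_spec(
        level, beta = config$maxent$beta,
        n_knots = config$maxent$n_knots)
    },
    brt_learning_rate = {
      config$brt$learning_rate <- level
    },
    brt_tree_complexity = {
      config$brt$tree_complexity <- as.integer(level)
    },
    brt_bag_fraction = {
      config$brt$bag_fraction <- level
    },
    brt_n_trees = {
      config$brt$n_trees <- as.integer(level)
    },
    mesh_cutoff = {
      config$gmrf$mesh_cutoff <- level
    }
  )
  config
}

level_label <- function(level) {
  if (is.character(level)) paste(level, collapse = "")
  else paste(format(level), collapse = "")
}

#' Run a configuration sweep over a simulated batch
#'
#' Refits the engines affected by the axis at every level, holding all other
#' settings at `base_config`, and scores each fit on the species' validation
#' set.
#'
#' @param batch An [simulate_species_batch()] result.
#' @param sweep A [sweep_grid()].
#' @param base_config An [sdm_config()].
#' @return A tibble: `species_id`, `method`, `axis`, `level` (label),
#'   `config_id`, `auc`, plus `fit_detail` columns where the engine reports
#'   them (non-zero feature counts for the MaxEnt-style engine).
#' @export
run_sweep <- function(batch, sweep, base_config = sdm_config()) {
  stopifnot(inherits(sweep, "sweep_grid"))
  methods <- sweep_methods(sweep$axis, base_config$methods)
  if (length(methods) == 0) {
    stop("no configured engine is affected by axis ", sweep$axis,
         call. = FALSE)
  }
  lv <- sweep$levels
  if (!is.list(lv)) lv <- as.list(lv)
  purrr::map_dfr(lv, function(level) {
    cfg <- apply_sweep_level(base_config, sweep$axis, level)
    purrr::map_dfr(batch, function(sp) {
      fits <- fit_species_models(sp, cfg, methods)
      res <- evaluate_species(fits, sp$validation,
                              species_id = sp$species_id)
      res$axis <- sweep$axis
      res$level <- level_label(level)
      res$config_id <- paste0(sweep$axis, "=", level_label(level))
      res$n_nonzero <- purrr::map_int(
        fits[res$method],
        ~ as.integer(.x$fit_info$n_nonzero %||% NA_integer_))
      res
    })
  })
}
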