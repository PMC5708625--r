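#' Settings for the boosted-regression-tree engine
#'
#' Defaults sit mid-range of the conventional sweeps: slow learning, shallow
#' trees, three-quarter bagging, a fixed number of trees with no internal
#' early stopping.
#'
#' @param learning_rate Shrinkage per tree (> 0, default 0.01).
#' @param tree_complexity Maximum tree depth / interaction depth (default 3).
#' @param bag_fraction Per-tree row subsample fraction in (0, 1]
#'   (default 0.75).
#' @param n_trees Number of boosting rounds (default 1000).
#' @return A list of class `brt_settings`.
#' @export
brt_settings <- function(learning_rate = 0.01, tree_complexity = 3,
                         bag_fraction = 0.75, n_trees = 1000) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("`learning_rate` must be > 0", call. = FALSE)
  }
  if (tree_complexity < 1) stop("`tree_complexity` must be >= 1",
                                call. = FALSE)
  if (bag_fraction <= 0 || bag_fraction > 1) {
    stop("`bag_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (n_trees < 1) stop("`n_trees` must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 tree_complexity = as.integer(tree_complexity),
                 bag_fraction = bag_fraction,
                 n_trees = as.integer(n_trees)),
            class = "brt_settings")
}

#' Fit the boosted-regression-tree engine
#'
#' Gradient-boosted classification trees (logistic loss) on the design
#' matrix, delegated to xgboost with exact greedy splits (so predictions
#' depend on predictor order statistics only) and a single thread for
#' reproducibility. The four conventional knobs map to `eta`, `max_depth`,
#' `subsample` and `nrounds`.
#'
#' @param y Binary labels, both classes present.
#' @param design A [build_design()] object.
#' @param covariates Covariate stack for the per-cell prediction surface.
#' @param settings A [brt_settings()].
#' @param rng_seed Integer seed for bagging.
#' @return A `fitted_sdm`; `fit_info` holds gain importance per predictor.
#' @export
fit_brt <- function(y, design, covariates, settings = brt_settings(),
                    rng_seed = 1) {
  stopifnot(inherits(design, "sdm_design"),
            inherits(settings, "brt_settings"))
  check_two_classes(y)
  params <- list(objective = "binary:logistic",
                 eta = settings$learning_rate,
                 max_depth = settings$tree_complexity,
                 subsample = settings$bag_fraction,
                 tree_method = "exact", nthread = 1,
                 seed = rng_seed)
  booster <- withr::with_seed(rng_seed,
    xgboost::xgb.train(params = params,
                       data = xgboost::xgb.DMatrix(design$X, label = y),
                       nrounds = settings$n_trees, verbose = 0))
  imp <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  Xc <- design_matrix_cells(design, covariates)
  prediction <- as.numeric(stats::predict(booster, Xc))
  new_fitted_sdm(
    method = "brt",
    prediction = pmin(pmax(prediction, 0), 1),
    fit_info = list(importance = imp, n_train = length(y),
                    settings = settings),
    config = list(design = design[c("spec", "terms", "center", "scale")],
                  settings = settings, rng_seed = rng_seed),
    design = design,
    predictor = function(covs) {
      as.numeric(stats::predict(booster, design_matrix_cells(design, covs)))
    }
  )
}
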