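#' Feature specification for the MaxEnt-style engine
#'
#' Feature classes follow the MaxEnt conventions: `L` linear, `Q` quadratic,
#' `P` pairwise products, `T` threshold indicators and `H` two-sided hinges
#' at quantile knots, and `AF` ("auto features") which resolves to a concrete
#' set by presence count: fewer than 10 presences `{L}`, fewer than 15
#' `{L,Q}`, fewer than 80 `{L,Q,H}`, otherwise `{L,Q,H,P,T}`.
#'
#' @param classes Character subset of `c("L","Q","P","T","H","AF")`; `AF`
#'   must be used alone.
#' @param beta Regularisation multiplier (> 0, default 1); larger values
#'   shrink more features to zero.
#' @param n_knots Number of quantile knots for hinge/threshold features
#'   (default 10, >= 2).
#' @return A list of class `maxent_feature_spec`.
#' @export
maxent_feature_spec <- function(classes = "AF", beta = 1, n_knots = 10) {
  classes <- unique(toupper(classes))
  bad <- setdiff(classes, c("L", "Q", "P", "T", "H", "AF"))
  if (length(classes) == 0 || length(bad) > 0) {
    stop("unknown feature class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if ("AF" %in% classes && length(classes) > 1) {
    stop("`AF` is exclusive of other feature classes", call. = FALSE)
  }
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be > 0",
                                           call. = FALSE)
  if (n_knots < 2) stop("`n_knots` must be >= 2", call. = FALSE)
  structure(list(classes = classes, beta = beta,
                 n_knots = as.integer(n_knots)),
            class = "maxent_feature_spec")
}

resolve_feature_classes <- function(classes, n_presence) {
  if (!identical(classes, "AF")) return(classes)
  if (n_presence < 10) "L"
  else if (n_presence < 15) c("L", "Q")
  else if (n_presence < 80) c("L", "Q", "H")
  else c("L", "Q", "H", "P", "T")
}

#' Expand covariate values into MaxEnt-style features
#'
#' Builds the feature matrix for the given classes. Knots for `T`/`H` are
#' the `n_knots` interior quantiles of each covariate over the supplied
#' rows. All features are rescaled to `[0, 1]` (MaxEnt convention); the
#' recipe (knots, offsets, ranges) is attached so the same expansion can be
#' replayed at prediction cells.
#'
#' @param X Numeric matrix of raw covariate values (rows = points).
#' @param spec A [maxent_feature_spec()].
#' @param n_presence Presence count used to resolve `AF` (default
#'   `nrow(X)`).
#' @param recipe Optional recipe from a previous expansion; when given, its
#'   knots and scaling are replayed instead of recomputed.
#' @return Feature matrix with attribute `recipe`.
#' @export
expand_maxent_features <- function(X, spec, n_presence = nrow(X),
                                   recipe = NULL) {
  stopifnot(inherits(spec, "maxent_feature_spec"))
  k <- ncol(X)
  cn <- colnames(X) %||% paste0("cov", seq_len(k))
  if (is.null(recipe)) {
    classes <- resolve_feature_classes(spec$classes, n_presence)
    knots <- lapply(seq_len(k), function(j) {
      unique(stats::quantile(X[, j],
                             probs = seq_len(spec$n_knots) /
                               (spec$n_knots + 1), names = FALSE))
    })
  } else {
    classes <- recipe$classes
    knots <- recipe$knots
  }
  feats <- list()
  if ("L" %in% classes) {
    L <- X; colnames(L) <- cn
    feats <- c(feats, list(L))
  }
  if ("Q" %in% classes) {
    Q <- X^2; colnames(Q) <- paste0(cn, "^2")
    feats <- c(feats, list(Q))
  }
  if ("P" %in% classes && k >= 2) {
    ij <- utils::combn(k, 2)
    P <- X[, ij[1, ], drop = FALSE] * X[, ij[2, ], drop = FALSE]
    colnames(P) <- paste0(cn[ij[1, ]], ":", cn[ij[2, ]])
    feats <- c(feats, list(P))
  }
  if ("T" %in% classes) {
    Tm <- do.call(cbind, lapply(seq_len(k), function(j) {
      out <- outer(X[, j], knots[[j]], `>`) * 1
      colnames(out) <- paste0("t(", cn[j], ">",
                              signif(knots[[j]], 4), ")")
      out
    }))
    feats <- c(feats, list(Tm))
  }
  if ("H" %in% classes) {
    Hm <- do.call(cbind, lapply(seq_len(k), function(j) {
      up <- pmax(outer(X[, j], knots[[j]], `-`), 0)
      dn <- pmax(-outer(X[, j], knots[[j]], `-`), 0)
      colnames(up) <- paste0("h(", cn[j], "-", signif(knots[[j]], 4), ")")
      colnames(dn) <- paste0("h(", signif(knots[[j]], 4), "-", cn[j], ")")
      cbind(up, dn)
    }))
    feats <- c(feats, list(Hm))
  }
  F <- do.call(cbind, feats)
  if (is.null(recipe)) {
    lo <- apply(F, 2, min)
    rng <- apply(F, 2, max) - lo
    rng[rng == 0] <- 1
    recipe <- list(classes = classes, knots = knots, lo = lo, rng = rng)
  }
  F <- sweep(sweep(F, 2, recipe$lo), 2, recipe$rng, "/")
  attr(F, "recipe") <- recipe
  F
}

# L1-penalised logistic regression by IRLS + coordinate descent.
# Minimises -(1/n) loglik + sum_j lambda_j |w_j| (intercept unpenalised).
lasso_logistic_cd <- function(y, F, lambda, max_outer = 100, tol = 1e-6) {
  n <- nrow(F); p <- ncol(F)
  w <- numeric(p); b0 <- stats::qlogis(pmin(pmax(mean(y), 0.01), 0.99))
  eta <- rep(b0, n)
  xsq <- colSums(F^2)
  for (outer in seq_len(max_outer)) {
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-5)
    zres <- (y - mu) / v          # working residual scale
    # quadratic-approximation coordinate descent sweeps
    for (sweep_i in 1:3) {
      delta_max <- 0
      # intercept
      db <- sum(v * zres) / sum(v)
      b0 <- b0 + db; zres <- zres - db
      delta_max <- max(delta_max, abs(db))
      for (j in seq_len(p)) {
        wj_old <- w[j]
        aj <- sum(v * F[, j]^2) / n
        if (aj <= 0) next
        cj <- sum(v * F[, j] * zres) / n + aj * wj_old
        wj_new <- soft_threshold(cj, lambda[j]) / aj
        if (wj_new != wj_old) {
          zres <- zres - F[, j] * (wj_new - wj_old)
          w[j] <- wj_new
          delta_max <- max(delta_max, abs(wj_new - wj_old))
        }
      }
      if (delta_max < tol) break
    }
    eta_new <- b0 + as.numeric(F %*% w)
    if (max(abs(eta_new - eta)) < tol) {
      eta <- eta_new
      break
    }
    eta <- eta_new
  }
  list(intercept = b0, weights = w, n_iter = outer)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Fit the MaxEnt-style regularised feature model
#'
#' Labels presences 1 and background 0, expands the covariates at those
#' points into the requested feature classes, and fits an L1-penalised
#' logistic regression by coordinate descent with the MaxEnt-style
#' per-feature penalty `lambda_j = beta * sqrt(var_j / n_presence)` (feature
#' variance over the presence points). The prediction surface is the
#' logistic output per cell.
#'
#' @param presences Data frame with `x`, `y` of presence points (>= 2).
#' @param background Background tibble from [generate_background()].
#' @param covariates Covariate stack.
#' @param spec A [maxent_feature_spec()].
#' @param covariate_subset Indices of layers to use (default all).
#' @return A `fitted_sdm`; `fit_info` holds the non-zero feature weights and
#'   their count.
#' @export
fit_maxent_like <- function(presences, background, covariates,
                            spec = maxent_feature_spec(),
                            covariate_subset = NULL) {
  stopifnot(inherits(covariates, "covariate_stack"),
            inherits(spec, "maxent_feature_spec"))
  if (nrow(presences) < 2) stop("need >= 2 presence points", call. = FALSE)
  if (nrow(background) < 1) stop("background is empty", call. = FALSE)
  sub <- covariate_subset %||% seq_len(ncol(covariates$values))
  pts <- dplyr::bind_rows(presences[, c("x", "y")],
                          background[, c("x", "y")])
  y <- c(rep(1, nrow(presences)), rep(0, nrow(background)))
  cells <- point_to_cell(covariates$grid, pts$x, pts$y)
  if (anyNA(cells)) stop("points fall outside the grid", call. = FALSE)
  Xraw <- covariates$values[cells, sub, drop = FALSE]
  F <- expand_maxent_features(Xraw, spec, n_presence = nrow(presences))
  recipe <- attr(F, "recipe")
  keep <- apply(F[y == 1, , drop = FALSE], 2, stats::var)
  pres_var <- ifelse(is.finite(keep), keep, 0)
  nonconstant <- apply(F, 2, function(col) max(col) > min(col))
  if (!any(nonconstant)) {
    stop("all expanded features are constant (degenerate design)",
         call. = FALSE)
  }
  # MaxEnt-style penalty, defined against the per-presence-scaled
  # log-likelihood; rescaled here to the per-observation objective the
  # coordinate descent minimises. The presence variance is floored so that
  # features constant over the presences (e.g. hinges knotted outside the
  # presence range) remain penalised and beta -> Inf shrinks every weight.
  lambda <- spec$beta * sqrt(pmax(pres_var, 1e-4) / nrow(presences)) *
    nrow(presences) / length(y)
  fit <- lasso_logistic_cd(y, F[, nonconstant, drop = FALSE],
                           lambda[nonconstant])
  w_full <- numeric(ncol(F)); w_full[nonconstant] <- fit$weights
  names(w_full) <- colnames(F)

  Fc <- expand_maxent_features(covariates$values[, sub, drop = FALSE],
                               spec, recipe = recipe)
  prediction <- stats::plogis(fit$intercept + as.numeric(Fc %*% w_full))
  new_fitted_sdm(
    method = "maxent_like",
    prediction = prediction,
    fit_info = list(weights = w_full[w_full != 0],
                    all_weights = w_full, intercept = fit$intercept,
                    n_nonzero = sum(w_full != 0),
                    iterations = fit$n_iter, n_train = length(y)),
    config = list(spec = spec, covariate_subset = sub, recipe = recipe),
    predictor = function(covs) {
      Fc2 <- expand_maxent_features(covs$values[, sub, drop = FALSE],
                                    spec, recipe = recipe)
      stats::plogis(fit$intercept + as.numeric(Fc2 %*% w_full))
    }
  )
}
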