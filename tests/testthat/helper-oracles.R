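# Independent oracles used across test files.

# AUC by explicit enumeration of all presence-absence pairs.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}

# Exact log posterior of the ridge-prior logistic model (used to check the
# Laplace mode against direct maximisation).
logistic_log_posterior <- function(beta, y, X, prior_sd) {
  eta <- as.numeric(X %*% beta)
  sum(y * eta - log1p(exp(eta))) - sum(beta^2) / (2 * prior_sd^2)
}

# Brute-force 2-parameter posterior maximiser: iteratively zoomed grid.
grid_maximise_2d <- function(y, X, prior_sd, lim = 10, steps = 6) {
  centre <- c(0, 0)
  width <- lim
  for (s in seq_len(steps)) {
    g1 <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    g2 <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    vals <- outer(g1, g2, Vectorize(function(a, b) {
      logistic_log_posterior(c(a, b), y, X, prior_sd)
    }))
    best <- arrayInd(which.max(vals), dim(vals))
    centre <- c(g1[best[1]], g2[best[2]])
    width <- width / 10
  }
  centre
}

# A minimal identity-transform design around a plain matrix, for engine
# tests that need full control of the predictors.
identity_design <- function(covariates, points,
                            subset = seq_len(ncol(covariates$values))) {
  terms <- tibble::tibble(kind = "linear", i = subset, j = NA_integer_)
  terms$term <- paste0("cov", subset)
  cells <- point_to_cell(covariates$grid, points$x, points$y)
  X <- covariates$values[cells, subset, drop = FALSE]
  colnames(X) <- terms$term
  structure(list(X = X,
                 spec = design_spec(subset, FALSE, FALSE),
                 terms = terms,
                 center = stats::setNames(rep(0, length(subset)),
                                          terms$term),
                 scale = stats::setNames(rep(1, length(subset)),
                                         terms$term)),
            class = "sdm_design")
}

# Small shared config for fast pipeline-level tests.
fast_config <- function(...) {
  sdm_config(n_background = 200,
             brt = brt_settings(n_trees = 100),
             ...)
}
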