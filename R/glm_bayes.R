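#' Fit a non-spatial Bayesian binomial GLM by Laplace approximation
#'
#' Bayesian logistic regression of presence (1) vs background (0) labels on
#' a design matrix, with independent Gaussian(0, `prior_sd_beta`^2) priors on
#' the intercept and every coefficient. The posterior is approximated by the
#' Laplace method: Newton ascent to the posterior mode with the Gaussian
#' curvature (negative Hessian) at the mode supplying posterior standard
#' deviations. The prediction surface is the inverse logit at the posterior
#' mode applied to every grid cell.
#'
#' @param y Binary response vector (both classes present).
#' @param design An [build_design()] object (its `X` has no intercept
#'   column; one is added internally and receives the same prior).
#' @param covariates The [generate_covariates()] stack used to build the
#'   design; needed to materialise the per-cell prediction surface.
#' @param prior_sd_beta Prior standard deviation (default 10 — weakly
#'   informative on standardized predictors).
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return A `fitted_sdm` object (see [predict_surface()]); `fit_info`
#'   carries the posterior mode, posterior sd, iterations and gradient norm.
#' @export
fit_nonspatial_bayes_glm <- function(y, design, covariates,
                                     prior_sd_beta = 10,
                                     max_iter = 50, tol = 1e-8) {
  stopifnot(inherits(design, "sdm_design"))
  check_two_classes(y)
  X <- cbind(`(Intercept)` = 1, design$X)
  fit <- laplace_logistic(y, X, prior_prec = 1 / prior_sd_beta^2,
                          max_iter = max_iter, tol = tol)
  Xc <- cbind(1, design_matrix_cells(design, covariates))
  prediction <- stats::plogis(as.numeric(Xc %*% fit$beta))
  new_fitted_sdm(
    method = "nonspatial_bayes_glm",
    prediction = prediction,
    fit_info = list(beta = fit$beta, beta_sd = fit$beta_sd,
                    iterations = fit$iterations,
                    grad_norm = fit$grad_norm,
                    log_posterior = fit$log_posterior,
                    prior_sd_beta = prior_sd_beta),
    config = list(design = design[c("spec", "terms", "center", "scale")],
                  prior_sd_beta = prior_sd_beta),
    design = design
  )
}

check_two_classes <- function(y) {
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    stop("`y` must contain both classes (0 and 1)", call. = FALSE)
  }
  invisible(TRUE)
}

# Newton ascent on the log posterior of a ridge-penalised logistic model.
laplace_logistic <- function(y, X, prior_prec, max_iter = 50, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  log_post <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * prior_prec * sum(b^2)
  }
  lp_old <- log_post(beta)
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    g <- as.numeric(crossprod(X, y - mu)) - prior_prec * beta
    grad_norm <- sqrt(sum(g^2))
    if (grad_norm < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * sqrt(w)) + diag(prior_prec, p)
    step <- solve(H, g)
    # halving line search on the log posterior
    s <- 1
    repeat {
      cand <- beta + s * step
      if (log_post(cand) >= lp_old - 1e-12 || s < 1e-6) break
      s <- s / 2
    }
    beta <- beta + s * step
    lp_old <- log_post(beta)
  }
  if (grad_norm >= 1e-4) {
    stop(sprintf("Newton ascent did not converge (gradient norm %.3g)",
                 grad_norm), call. = FALSE)
  }
  eta <- as.numeric(X %*% beta)
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
  H <- crossprod(X * sqrt(w)) + diag(prior_prec, p)
  beta_sd <- sqrt(diag(solve(H)))
  names(beta) <- names(beta_sd) <- colnames(X)
  list(beta = beta, beta_sd = beta_sd, iterations = it,
       grad_norm = grad_norm, log_posterior = lp_old, hessian = H)
}
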