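#' Fit a spatial Bayesian binomial GLM with a GMRF random field
#'
#' Logistic model `logit(p_i) = X_i beta + A_i u` where `u` is a Gaussian
#' Markov random field on a regular mesh with precision
#' `Q(kappa, tau)` (see [build_gmrf_precision()]) and `A` the bilinear
#' projector from mesh nodes to data locations. For each `(kappa, tau)` pair
#' on a log-scale grid the joint posterior mode of `(beta, u)` is found by
#' Newton ascent and the pair is scored by the Laplace-approximated marginal
#' likelihood; the best pair is selected — an empirical-Bayes analogue of
#' fitting the hyperparameters jointly with the regression. The prediction
#' surface is the inverse logit of `X beta + A u` at the joint mode, on
#' every grid cell.
#'
#' @param y Binary labels (presence 1, background 0), both classes present.
#' @param design A [build_design()] object for the same points.
#' @param covariates The covariate stack (defines the grid and the per-cell
#'   prediction).
#' @param points Data frame with `x`, `y` of the data locations, in the same
#'   order as `y`.
#' @param spec A [gmrf_spec()].
#' @return A `fitted_sdm`; `fit_info` holds the selected hyperparameters,
#'   the grid of log marginal likelihoods with normalised weights, the fixed
#'   effect posterior summaries and the field mode.
#' @export
fit_spatial_bayes_glm <- function(y, design, covariates, points,
                                  spec = gmrf_spec()) {
  stopifnot(inherits(design, "sdm_design"),
            inherits(covariates, "covariate_stack"),
            inherits(spec, "gmrf_spec"))
  check_two_classes(y)
  grid <- covariates$grid
  mesh <- build_mesh(grid, spec$mesh_cutoff)
  mm <- mesh_matrices(mesh)
  A <- mesh_projector(mesh, points$x, points$y)
  X <- cbind(`(Intercept)` = 1, design$X)
  p <- ncol(X); m <- mesh$n_nodes
  B <- cbind2(methods::as(X, "CsparseMatrix"), A)
  lambda <- 1 / spec$prior_sd_beta^2

  hyper <- hyper_grid(grid, spec)
  ext <- grid_extent(grid)
  rho0_default <- min(ext["xmax"] - ext["xmin"],
                      ext["ymax"] - ext["ymin"]) / 5
  z <- numeric(p + m)
  best <- list(score = -Inf)
  scores <- numeric(nrow(hyper))
  for (r in seq_len(nrow(hyper))) {
    kap <- hyper$kappa[r]; tau <- hyper$tau[r]
    Q <- tau * (kap^4 * mm$C + 2 * kap^2 * mm$G +
                  mm$G %*% Matrix::solve(mm$C, mm$G))
    Q <- Matrix::forceSymmetric(Q)
    fit <- tryCatch(
      newton_joint(y, B, p, Q, lambda, z_init = z),
      error = function(e) {
        stop(sprintf("spatial fit failed at kappa=%.3g tau=%.3g: %s",
                     kap, tau, conditionMessage(e)), call. = FALSE)
      })
    z <- fit$z
    ld_q <- as.numeric(Matrix::determinant(Q, logarithm = TRUE)$modulus)
    scores[r] <- fit$log_posterior + 0.5 * ld_q + 0.5 * p * log(lambda) -
      0.5 * fit$logdet_H +
      log_hyper_prior(kap, tau, spec, rho0_default)
    if (scores[r] > best$score) {
      best <- list(score = scores[r], row = r, fit = fit, Q = Q)
    }
  }
  hyper$log_post <- scores
  hyper$weight <- exp(scores - max(scores))
  hyper$weight <- hyper$weight / sum(hyper$weight)

  fit <- best$fit
  beta <- fit$z[seq_len(p)]
  u <- fit$z[-seq_len(p)]
  names(beta) <- colnames(X)
  # posterior sd of the fixed effects from the joint Hessian
  Hinv_cols <- Matrix::solve(fit$H, Matrix::Diagonal(p + m)[, seq_len(p)])
  beta_sd <- sqrt(Matrix::diag(Hinv_cols[seq_len(p), , drop = FALSE]))
  names(beta_sd) <- colnames(X)

  cc <- cell_centres(grid)
  A_cells <- mesh_projector(mesh, cc$x, cc$y)
  Xc <- cbind(1, design_matrix_cells(design, covariates))
  prediction <- stats::plogis(as.numeric(Xc %*% beta) +
                                as.numeric(A_cells %*% u))
  new_fitted_sdm(
    method = "spatial_bayes_glm",
    prediction = prediction,
    fit_info = list(beta = beta, beta_sd = beta_sd, u = u,
                    kappa = hyper$kappa[best$row], tau = hyper$tau[best$row],
                    hyper_grid = hyper, iterations = fit$iterations,
                    grad_norm = fit$grad_norm,
                    log_posterior = fit$log_posterior,
                    log_ml = best$score, n_train = length(y)),
    config = list(design = design[c("spec", "terms", "center", "scale")],
                  gmrf = spec, mesh = mesh),
    design = design,
    predictor = NULL
  )
}

# Log-scale hyperparameter grid centred on landscape-scale heuristics:
# effective range ~ a fifth of the shorter landscape side, unit field sd.
hyper_grid <- function(grid, spec) {
  if (!is.null(spec$kappa_fixed) && !is.null(spec$tau_fixed)) {
    return(tibble::tibble(kappa = spec$kappa_fixed, tau = spec$tau_fixed))
  }
  ext <- grid_extent(grid)
  short <- min(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"])
  kappa0 <- sqrt(8) / (short / 5)
  tau0 <- 1 / (4 * pi * kappa0^2)
  mult <- exp(seq(-spec$grid_span, spec$grid_span,
                  length.out = spec$n_grid))
  g <- tidyr::expand_grid(kappa = kappa0 * mult, tau = tau0 * mult)
  if (!is.null(spec$kappa_fixed)) g$kappa <- spec$kappa_fixed
  if (!is.null(spec$tau_fixed)) g$tau <- spec$tau_fixed
  dplyr::distinct(g)
}

# Newton ascent to the joint mode of (beta, u); returns the mode, the joint
# Hessian at the mode and its log determinant.
newton_joint <- function(y, B, p, Q, lambda, z_init = NULL,
                         max_iter = 60, tol = 1e-8) {
  n <- length(y); m <- ncol(B) - p
  P <- Matrix::bdiag(Matrix::Diagonal(p, lambda), Q)
  z <- if (is.null(z_init)) numeric(p + m) else z_init
  log_post <- function(zz) {
    eta <- as.numeric(B %*% zz)
    sum(y * eta - log1p(exp(eta))) -
      0.5 * as.numeric(zz %*% (P %*% zz))
  }
  lp_old <- log_post(z)
  grad_norm <- Inf
  H <- NULL
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(B %*% z)
    mu <- stats::plogis(eta)
    g <- as.numeric(Matrix::crossprod(B, y - mu)) - as.numeric(P %*% z)
    grad_norm <- sqrt(sum(g^2))
    if (grad_norm < tol && !is.null(H)) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- Matrix::forceSymmetric(
      Matrix::crossprod(B, B * w) + P)
    step <- as.numeric(Matrix::solve(H, g))
    s <- 1
    repeat {
      cand <- z + s * step
      if (log_post(cand) >= lp_old - 1e-12 || s < 1e-6) break
      s <- s / 2
    }
    z <- z + s * step
    lp_old <- log_post(z)
    if (grad_norm < tol) break
  }
  if (grad_norm >= 1e-4) {
    stop(sprintf("joint Newton did not converge (gradient norm %.3g)",
                 grad_norm), call. = FALSE)
  }
  logdet_H <- as.numeric(Matrix::determinant(H, logarithm = TRUE)$modulus)
  list(z = z, H = H, logdet_H = logdet_H, iterations = it,
       grad_norm = grad_norm, log_posterior = lp_old)
}
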