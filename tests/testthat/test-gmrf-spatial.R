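test_that("GMRF precision is symmetric positive definite and linear in tau", {
  g <- grid_spec(40, 20)
  Q <- build_gmrf_precision(g, mesh_cutoff = 4, kappa = 1, tau = 2)
  expect_equal(max(abs(Q - Matrix::t(Q))), 0)
  ch <- tryCatch(Matrix::Cholesky(Q), error = function(e) NULL)
  expect_false(is.null(ch))
  Q2 <- build_gmrf_precision(g, mesh_cutoff = 4, kappa = 1, tau = 4)
  expect_lt(max(abs(Q2 - 2 * Q)), 1e-10)
  expect_error(build_gmrf_precision(g, 4, -1, 1), "kappa")
})

test_that("larger kappa shortens the field's correlation range", {
  g <- grid_spec(40, 40)
  ranges <- vapply(c(0.25, 0.5, 1), function(kap) {
    tau <- 1 / (4 * pi * kap^2)  # unit marginal variance
    Q <- build_gmrf_precision(g, mesh_cutoff = 2, kappa = kap, tau = tau)
    S <- solve(as.matrix(Q))
    mesh <- attr(Q, "mesh")
    # correlation along one mesh row from a central node
    i0 <- (mesh$ny %/% 2) * mesh$nx + 3
    cors <- vapply(0:(mesh$nx - 4), function(dd) {
      S[i0, i0 + dd] / sqrt(S[i0, i0] * S[i0 + dd, i0 + dd])
    }, numeric(1))
    dist <- (0:(mesh$nx - 4)) * mesh$dx
    # distance where correlation first drops below 0.14 ~ effective range
    dist[which(cors < 0.14)[1]]
  }, numeric(1))
  expect_true(all(diff(ranges) < 0))
})

test_that("spatial fit degenerates to the non-spatial fit when the field is pinned", {
  g <- grid_spec(40, 20)
  cs <- generate_covariates(g, 3, rng_seed = 21)
  set.seed(2)
  pts <- cell_centres(g)[sample.int(800, 400), c("x", "y")]
  d <- build_design(cs, pts, design_spec(1:3, TRUE, FALSE))
  y <- rbinom(400, 1, plogis(0.8 * d$X[, 1] - 0.5 * d$X[, 2]))
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  flat <- fit_nonspatial_bayes_glm(y, d, cs, prior_sd_beta = 10)
  pinned <- fit_spatial_bayes_glm(
    y, d, cs, pts,
    spec = gmrf_spec(mesh_cutoff = 4, prior_sd_beta = 10,
                     kappa_fixed = 1, tau_fixed = 1e8))
  expect_lt(max(abs(pinned$prediction - flat$prediction)), 1e-3)
})

test_that("empirical-Bayes selection recovers the generating kappa", {
  g <- grid_spec(40, 20)
  cs <- generate_covariates(g, 2, rng_seed = 31)
  cc <- cell_centres(g)
  cutoff <- 4
  kap_star <- 0.5
  tau_star <- 1 / (4 * pi * kap_star^2)  # unit field variance
  Q_star <- build_gmrf_precision(g, cutoff, kap_star, tau_star)
  mesh <- attr(Q_star, "mesh")
  hits <- 0
  n_rep <- 20
  grid_step <- exp(1)  # spec: 5-point grid spanning exp(+/-2)
  for (r in seq_len(n_rep)) {
    u <- sdmbench:::simulate_gmrf(Q_star, rng_seed = 100 + r)
    set.seed(200 + r)
    idx <- sample.int(nrow(cc), 2000, replace = TRUE)
    pts <- cc[idx, c("x", "y")]
    A <- sdmbench:::mesh_projector(mesh, pts$x, pts$y)
    d <- build_design(cs, pts, design_spec(1:2, FALSE, FALSE))
    eta <- 0.5 * d$X[, 1] + as.numeric(A %*% u)
    y <- rbinom(2000, 1, plogis(eta))
    fit <- fit_spatial_bayes_glm(
      y, d, cs, pts,
      spec = gmrf_spec(mesh_cutoff = cutoff, n_grid = 5, grid_span = 2))
    # centre the comparison on the hyper grid actually searched
    sel <- fit$fit_info$kappa
    ratio <- sel / kap_star
    if (ratio <= grid_step * 1.001 && ratio >= 1 / (grid_step * 1.001)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 0.8 * n_rep)
})

test_that("marginal-likelihood scoring is deterministic", {
  g <- grid_spec(30, 15)
  cs <- generate_covariates(g, 2, rng_seed = 5)
  set.seed(9)
  pts <- cell_centres(g)[sample.int(450, 300, replace = TRUE), c("x", "y")]
  d <- build_design(cs, pts, design_spec(1:2, FALSE, FALSE))
  y <- rbinom(300, 1, plogis(d$X[, 1]))
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  spec <- gmrf_spec(mesh_cutoff = 4, n_grid = 3, grid_span = 1.5)
  f1 <- fit_spatial_bayes_glm(y, d, cs, pts, spec)
  f2 <- fit_spatial_bayes_glm(y, d, cs, pts, spec)
  expect_identical(f1$fit_info$log_ml, f2$fit_info$log_ml)
  expect_identical(f1$prediction, f2$prediction)
  expect_true(all(f1$prediction >= 0 & f1$prediction <= 1))
})
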