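test_that("feature expansion produces the documented column counts", {
  set.seed(3)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("cov", 1:5)))
  lq <- expand_maxent_features(X, maxent_feature_spec(c("L", "Q")))
  expect_equal(ncol(lq), 10)
  expect_true(all(lq >= 0 & lq <= 1))

  h1 <- expand_maxent_features(X[, 1, drop = FALSE],
                               maxent_feature_spec("H", n_knots = 10))
  expect_equal(ncol(h1), 20)

  full <- expand_maxent_features(
    X, maxent_feature_spec(c("L", "Q", "P", "T", "H"), n_knots = 10))
  expect_equal(ncol(full), 5 + 5 + 10 + 50 + 100)

  expect_error(maxent_feature_spec("X"), "unknown feature class")
  expect_error(maxent_feature_spec(c("AF", "L")), "exclusive")
})

test_that("auto features resolve by presence count", {
  expect_equal(sdmbench:::resolve_feature_classes("AF", 5), "L")
  expect_equal(sdmbench:::resolve_feature_classes("AF", 12), c("L", "Q"))
  expect_equal(sdmbench:::resolve_feature_classes("AF", 40),
               c("L", "Q", "H"))
  expect_equal(sdmbench:::resolve_feature_classes("AF", 200),
               c("L", "Q", "H", "P", "T"))
  expect_equal(sdmbench:::resolve_feature_classes(c("L", "H"), 5),
               c("L", "H"))
})

test_that("coordinate descent agrees with an established lasso solver", {
  set.seed(14)
  n <- 400
  F <- matrix(runif(n * 12), n, 12)
  y <- rbinom(n, 1, plogis(-1 + 3 * F[, 1] - 2 * F[, 2]))
  lambda <- runif(12, 0.001, 0.02)
  fit <- sdmbench:::lasso_logistic_cd(y, F, lambda, tol = 1e-8)
  lam_bar <- mean(lambda)
  g <- glmnet::glmnet(F, y, family = "binomial", lambda = lam_bar,
                      penalty.factor = lambda / lam_bar,
                      standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(fit$weights - as.numeric(coef(g))[-1])), 1e-5)
  expect_lt(abs(fit$intercept - as.numeric(coef(g))[1]), 1e-5)
})

test_that("the number of active features is non-increasing in beta", {
  g <- grid_spec(60, 30)
  cs <- generate_covariates(g, 5, rng_seed = 41)
  m <- draw_species_model(enumerate_term_pool(5), 3)
  ts <- predict_truth_surface(m, cs, 0.25, 2)
  cc <- cell_centres(g)
  set.seed(8)
  pres_cells <- sample(which(ts$p_noisy > quantile(ts$p_noisy, 0.8)), 150)
  pres <- cc[pres_cells, c("x", "y")]
  bg <- generate_background(g, pres, "R", 500, 9)
  nz <- vapply(c(0.5, 1, 2, 4, 16), function(b) {
    f <- fit_maxent_like(pres, bg, cs,
                         maxent_feature_spec(c("L", "Q", "H"), beta = b))
    f$fit_info$n_nonzero
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("full shrinkage yields a constant surface and chance-level AUC", {
  g <- grid_spec(40, 20)
  cs <- generate_covariates(g, 3, rng_seed = 6)
  m <- draw_species_model(enumerate_term_pool(3), 5)
  ts <- predict_truth_surface(m, cs, 0.25, 2)
  cc <- cell_centres(g)
  set.seed(10)
  pres <- cc[sample.int(800, 60), c("x", "y")]
  bg <- generate_background(g, pres, "R", 300, 2)
  f <- fit_maxent_like(pres, bg, cs,
                       maxent_feature_spec(c("L", "Q"), beta = 1e6))
  expect_equal(f$fit_info$n_nonzero, 0)
  expect_lt(diff(range(f$prediction)), 1e-10)
  v <- sample_validation_points(ts, 500, 3)
  expect_equal(compute_auc(f$prediction[v$cell], v$label), 0.5)
})

test_that("a monotone single-covariate model recovers the coefficient sign", {
  g <- grid_spec(60, 30)
  cs <- generate_covariates(g, 1, rng_seed = 17)
  cs$values[, 1] <- sdmbench:::layer_field(g, 0, 0.05, 0.4)
  cc <- cell_centres(g)
  p <- plogis(2 * cs$values[, 1])
  set.seed(11)
  pres_cells <- sample.int(n_cells(g), 200, prob = p, replace = TRUE)
  pres <- cc[pres_cells, c("x", "y")]
  bg <- generate_background(g, pres, "R", 800, 3)
  f <- fit_maxent_like(pres, bg, cs, maxent_feature_spec("L", beta = 0.5))
  expect_gt(f$fit_info$all_weights[["cov1"]], 0)
})
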