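test_that("term pool enumerates linear, square and pairwise terms", {
  expect_equal(nrow(enumerate_term_pool(5)), 20)
  expect_equal(nrow(enumerate_term_pool(1)), 2)
  expect_equal(nrow(enumerate_term_pool(2)), 5)
  pool <- enumerate_term_pool(5)
  expect_equal(sum(pool$kind == "linear"), 5)
  expect_equal(sum(pool$kind == "square"), 5)
  expect_equal(sum(pool$kind == "interaction"), 10)
  ints <- pool[pool$kind == "interaction", ]
  expect_true(all(ints$i < ints$j))
  expect_false(any(duplicated(pool$term)))
})

test_that("covariate layers are standardized, finite and seed-deterministic", {
  g <- grid_spec(60, 30)
  cs <- generate_covariates(g, n_cov = 5, rng_seed = 1)
  expect_equal(ncol(cs$values), 5)
  expect_equal(nrow(cs$values), 1800)
  expect_true(all(is.finite(cs$values)))
  expect_true(all(abs(colMeans(cs$values)) < 1e-9))
  expect_true(all(abs(apply(cs$values, 2, sd) - 1) < 1e-9))
  cs2 <- generate_covariates(g, n_cov = 5, rng_seed = 1)
  expect_identical(cs$values, cs2$values)
  cs3 <- generate_covariates(g, n_cov = 5, rng_seed = 2)
  expect_false(identical(cs$values, cs3$values))
  expect_error(generate_covariates(g, 0, 1), "n_cov")
})

test_that("a left-right tail-window layer is monotone along every row", {
  g <- grid_spec(40, 12)
  v <- sdmbench:::layer_field(g, angle = 0, q_lo = 0.02, q_hi = 0.35)
  m <- matrix(v, nrow = 12, ncol = 40, byrow = TRUE)
  diffs <- t(apply(m, 1, diff))
  expect_true(all(diffs >= 0) || all(diffs <= 0))
  # window spanning the mode gives a hump: sign change in row differences
  vh <- sdmbench:::layer_field(g, angle = 0, q_lo = 0.2, q_hi = 0.9)
  dh <- diff(matrix(vh, 12, 40, byrow = TRUE)[1, ])
  expect_true(any(dh > 0) && any(dh < 0))
})

test_that("species model draws cover the pool uniformly over seeds", {
  pool <- enumerate_term_pool(3)  # 8 terms
  m <- draw_species_model(pool, rng_seed = 7)
  expect_true(nrow(m$terms) >= 1 && nrow(m$terms) <= nrow(pool))
  expect_false(any(duplicated(m$terms$term)))
  counts <- integer(nrow(pool))
  n_rep <- 3000
  for (s in seq_len(n_rep)) {
    sel <- draw_species_model(pool, rng_seed = s)$terms$term
    counts[match(sel, pool$term)] <- counts[match(sel, pool$term)] + 1
  }
  # marginal inclusion probability = E[k]/8 = 4.5/8
  p_hat <- counts / n_rep
  expect_true(all(abs(p_hat - 4.5 / 8) < 0.05))
  expect_error(draw_species_model(pool[0, ], 1), "non-empty")
})

test_that("truth surface composes the regression through the inverse logit", {
  g <- grid_spec(30, 20)
  cs <- generate_covariates(g, 3, rng_seed = 5)
  pool <- enumerate_term_pool(3)
  flat <- structure(list(terms = dplyr::mutate(pool[1, ], coefficient = 0),
                         intercept = 0), class = "species_model")
  ts <- predict_truth_surface(flat, cs, noise_sd = 0, rng_seed = 1)
  expect_equal(ts$p_clean, rep(0.5, n_cells(g)))
  expect_identical(ts$p_noisy, ts$p_clean)

  # single positive linear term on a monotone gradient layer
  mono_vals <- sdmbench:::layer_field(g, 0, 0.02, 0.3)
  cs$values[, 1] <- mono_vals
  m1 <- structure(list(terms = dplyr::mutate(pool[1, ], coefficient = 2),
                       intercept = 0), class = "species_model")
  ts1 <- predict_truth_surface(m1, cs, noise_sd = 0, rng_seed = 1)
  row1 <- matrix(ts1$p_clean, 20, 30, byrow = TRUE)[1, ]
  d <- diff(row1)
  expect_true(all(d >= 0) || all(d <= 0))
  expect_true(all(ts1$p_clean >= 0 & ts1$p_clean <= 1))

  # logit-scale noise keeps probabilities valid and is centred
  m_big <- structure(list(terms = dplyr::mutate(pool[1, ],
                                                coefficient = 10),
                          intercept = 0), class = "species_model")
  tsn <- predict_truth_surface(m_big, cs, noise_sd = 0.25, rng_seed = 2)
  expect_true(all(tsn$p_noisy >= 0 & tsn$p_noisy <= 1))

  bad <- structure(list(terms = dplyr::mutate(pool[1, ], i = 9,
                                              coefficient = 1),
                        intercept = 0), class = "species_model")
  expect_error(predict_truth_surface(bad, cs), "layer")
})

test_that("logit noise has median 0.5 at a logit-zero cell", {
  g <- grid_spec(100, 100)
  cs <- generate_covariates(g, 1, rng_seed = 3)
  flat <- structure(
    list(terms = dplyr::mutate(enumerate_term_pool(1)[1, ],
                               coefficient = 0), intercept = 0),
    class = "species_model")
  draws <- vapply(1:2000, function(s) {
    predict_truth_surface(flat, cs, noise_sd = 0.25,
                          rng_seed = s)$p_noisy[1]
  }, numeric(1))
  expect_lt(abs(median(draws) - 0.5), 0.01)
  expect_gt(sd(draws), 0)
})

test_that("validation sampling respects n, bounds and the labelling rule", {
  g <- grid_spec(90, 45)
  cs <- generate_covariates(g, 2, rng_seed = 11)
  pool <- enumerate_term_pool(2)
  m <- draw_species_model(pool, 3)
  ts <- predict_truth_surface(m, cs, noise_sd = 0.25, rng_seed = 4)
  v <- sample_validation_points(ts, n = 1000, rng_seed = 9)
  expect_equal(nrow(v), 1000)
  expect_false(any(duplicated(v$cell)))
  expect_true(all(v$label %in% 0:1))
  expect_identical(v$label, as.integer(ts$p_noisy[v$cell] > 0.5))
  expect_error(sample_validation_points(ts, n_cells(g) + 1), "exceeds")
})

test_that("bernoulli validation labels match binomial sampling", {
  g <- grid_spec(110, 100)
  cs <- generate_covariates(g, 1, rng_seed = 2)
  m03 <- structure(
    list(terms = dplyr::mutate(enumerate_term_pool(1)[1, ],
                               coefficient = 0),
         intercept = qlogis(0.3)), class = "species_model")
  ts <- predict_truth_surface(m03, cs, noise_sd = 0, rng_seed = 1)
  v <- sample_validation_points(ts, n = 10000, rng_seed = 5,
                                label_rule = "bernoulli")
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(v$label) - 0.3), 3 * se)

  # per-cell label frequency converges to p_noisy at fixed cells
  m_var <- draw_species_model(enumerate_term_pool(1), 8)
  g2 <- grid_spec(10, 10)
  cs2 <- generate_covariates(g2, 1, rng_seed = 3)
  ts2 <- predict_truth_surface(m_var, cs2, noise_sd = 0, rng_seed = 1)
  lab <- matrix(0L, 300, 3)
  cells <- c(1, 37, 100)
  for (s in 1:300) {
    vv <- sample_validation_points(ts2, n = 100, rng_seed = s,
                                   label_rule = "bernoulli")
    lab[s, ] <- vv$label[match(cells, vv$cell)]
  }
  freq <- colMeans(lab)
  expect_true(all(abs(freq - ts2$p_noisy[cells]) <
                    4 * sqrt(0.25 / 300) + 0.02))
})
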