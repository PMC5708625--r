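make_truth <- function(grid, p = NULL, seed = 1) {
  cs <- generate_covariates(grid, 1, rng_seed = seed)
  m <- structure(
    list(terms = dplyr::mutate(enumerate_term_pool(1)[1, ],
                               coefficient = 0), intercept = 0),
    class = "species_model")
  ts <- predict_truth_surface(m, cs, noise_sd = 0, rng_seed = 1)
  if (!is.null(p)) {
    ts$p_clean <- ts$p_noisy <- rep(p, n_cells(grid))
  }
  ts
}

test_that("reporting layer partitions the grid into six contiguous regions", {
  g <- grid_spec(60, 30)
  rl <- generate_reporting_layer(g, rng_seed = 3)
  expect_setequal(unique(rl$region_id), 1:6)
  expect_true(all(rl$rate >= 0 & rl$rate <= 1))
  expect_equal(rl$rate, rl$region_rates[rl$region_id])
  # Voronoi regions of the nearest-centre rule are 4-connected: every
  # cell's region also appears among its neighbours or is a singleton
  m <- matrix(rl$region_id, 30, 60, byrow = TRUE)
  # contiguity check: flood-fill each region and compare sizes
  for (r in 1:6) {
    cells <- which(m == r, arr.ind = TRUE)
    visited <- matrix(FALSE, 30, 60)
    stack <- list(cells[1, ])
    visited[cells[1, 1], cells[1, 2]] <- TRUE
    count <- 1
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nb <- cur + d
        if (nb[1] >= 1 && nb[1] <= 30 && nb[2] >= 1 && nb[2] <= 60 &&
            !visited[nb[1], nb[2]] && m[nb[1], nb[2]] == r) {
          visited[nb[1], nb[2]] <- TRUE
          count <- count + 1
          stack[[length(stack) + 1]] <- nb
        }
      }
    }
    expect_equal(count, nrow(cells))
  }
})

test_that("a fixed cell's reporting rate is Uniform(0,1) over seeds", {
  g <- grid_spec(20, 10)
  rates <- vapply(1:600, function(s) {
    generate_reporting_layer(g, rng_seed = s)$rate[57]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(rates, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("seed point counts follow the uniform-integer rule", {
  g <- grid_spec(30, 15)
  s1 <- draw_seed_points(g, 1)
  expect_true(nrow(s1) >= 5 && nrow(s1) <= 20)
  expect_equal(nrow(draw_seed_points(g, 2, 1, 1)), 1)
  counts <- vapply(1:4000, function(s) {
    nrow(draw_seed_points(g, s))
  }, numeric(1))
  freq <- tabulate(counts, 20)[5:20] / 4000
  expect_true(all(abs(freq - 1 / 16) < 4 * sqrt((1 / 16) * (15 / 16) / 4000)))
  expect_error(draw_seed_points(g, 1, 5, 4), "min_seeds")
})

test_that("seed filtering follows the reporting rate with a survivor fallback", {
  g <- grid_spec(30, 15)
  seeds <- draw_seed_points(g, 4, 20, 20)
  rl <- generate_reporting_layer(g, 1)
  rl$rate <- rep(1, n_cells(g))
  expect_true(all(filter_seeds(seeds, rl, 1)$retained))
  rl$rate <- rep(0, n_cells(g))
  expect_equal(sum(filter_seeds(seeds, rl, 1)$retained), 1)
  rl$rate <- rep(0.5, n_cells(g))
  kept <- vapply(1:2000, function(s) {
    sum(filter_seeds(seeds, rl, s)$retained)
  }, numeric(1))
  expect_lt(abs(mean(kept) - 10), 4 * sqrt(20 * 0.25 / 2000) + 0.05)
})

test_that("clumped sampling returns exactly n in-grid points", {
  g <- grid_spec(90, 45)
  ts <- make_truth(g, p = 0.8)
  seeds <- draw_seed_points(g, 3)
  seeds$retained <- TRUE
  for (mode in c("biological", "random")) {
    s <- draw_clumped_samples(seeds, clumping_params(10), ts, mode,
                              n_total = 25, rng_seed = 5)
    expect_equal(nrow(s), 25)
    expect_true(all(points_in_grid(g, s$x, s$y)))
  }
  s2 <- draw_clumped_samples(seeds, clumping_params(10), ts, "random",
                             n_total = 25, rng_seed = 5)
  expect_identical(
    as.data.frame(draw_clumped_samples(seeds, clumping_params(10), ts,
                                       "random", 25, 5)),
    as.data.frame(s2))
  expect_error(draw_clumped_samples(seeds, clumping_params(10), ts,
                                    "random", 10, 1), "n_total")
})

test_that("small clumping coefficients keep points within a tight radius", {
  g <- grid_spec(90, 45)
  ts <- make_truth(g, p = 1)
  seeds <- tibble::tibble(x = 45, y = 22.5, retained = TRUE)
  s <- draw_clumped_samples(seeds, clumping_params(1), ts, "random",
                            n_total = 500, rng_seed = 1)
  d <- sqrt((s$x - 45)^2 + (s$y - 22.5)^2)
  # displacement ~ |N(1, 0.2)|: essentially all mass below 2 cells
  expect_gt(mean(d <= 2), 0.99)
})

test_that("biological mode enriches suitability relative to random mode", {
  g <- grid_spec(90, 45)
  diffs <- vapply(1:40, function(i) {
    cs <- generate_covariates(g, 2, rng_seed = i)
    m <- draw_species_model(enumerate_term_pool(2), i)
    ts <- predict_truth_surface(m, cs, noise_sd = 0.25, rng_seed = i)
    if (mean(ts$p_noisy) < 0.02) return(NA_real_)
    seeds <- draw_seed_points(g, i)
    seeds$retained <- TRUE
    bio <- tryCatch(
      draw_clumped_samples(seeds, clumping_params(25), ts, "biological",
                           100, rng_seed = 1000 + i),
      error = function(e) NULL)
    if (is.null(bio)) return(NA_real_)
    rnd <- draw_clumped_samples(seeds, clumping_params(25), ts, "random",
                                100, rng_seed = 1000 + i)
    mean(ts$p_noisy[point_to_cell(g, bio$x, bio$y)]) -
      mean(ts$p_noisy[point_to_cell(g, rnd$x, rnd$y)])
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  expect_gt(length(diffs), 25)
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("unsampleable biological truth aborts with a budget diagnostic", {
  g <- grid_spec(30, 15)
  ts <- make_truth(g, p = 0)
  seeds <- tibble::tibble(x = 15, y = 7.5, retained = TRUE)
  expect_error(
    draw_clumped_samples(seeds, clumping_params(5), ts, "biological", 25,
                         rng_seed = 1, max_attempts = 2000),
    "exhausted")
})

test_that("clumping parameter validation and the c/5 sd rule hold", {
  cp <- clumping_params(10)
  expect_equal(cp$c_sd, 2)
  expect_error(clumping_params(0.5), "\\[1, 50\\]")
  expect_error(clumping_params(51), "\\[1, 50\\]")
})
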