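test_that("Clark-Evans index matches closed forms", {
  # 20 x 20 unit-spaced lattice on a matched window: r_obs = 1,
  # r_exp = 1/2, index = 2
  pts <- expand.grid(x = 1:20, y = 1:20)
  expect_lt(abs(clark_evans_index(pts, study_area = 400) - 2), 0.05)

  # coincident points
  co <- data.frame(x = rep(3, 5), y = rep(4, 5))
  expect_equal(clark_evans_index(co, 100), 0)

  expect_error(clark_evans_index(data.frame(x = 1, y = 1), 10), "2 points")
  expect_error(clark_evans_index(pts, 0), "study_area")
})

test_that("Clark-Evans is near 1 for complete spatial randomness", {
  set.seed(71)
  idx <- vapply(1:300, function(i) {
    pts <- data.frame(x = runif(500, 0, 90), y = runif(500, 0, 45))
    clark_evans_index(pts, 90 * 45)
  }, numeric(1))
  expect_lt(abs(mean(idx) - 1), 0.05)
})

test_that("Clark-Evans is invariant to rigid motions and scaling", {
  set.seed(5)
  pts <- data.frame(x = runif(60, 0, 10), y = runif(60, 0, 10))
  base <- clark_evans_index(pts, 100)
  shifted <- data.frame(x = pts$x + 13, y = pts$y - 4)
  expect_equal(clark_evans_index(shifted, 100), base)
  th <- 0.7
  rot <- data.frame(x = cos(th) * pts$x - sin(th) * pts$y,
                    y = sin(th) * pts$x + cos(th) * pts$y)
  expect_equal(clark_evans_index(rot, 100), base, tolerance = 1e-12)
  s <- 3.7
  expect_equal(clark_evans_index(data.frame(x = s * pts$x, y = s * pts$y),
                                 100 * s^2), base, tolerance = 1e-12)
})

test_that("convex-hull coverage uses shoelace areas", {
  unit_sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  big_sq <- data.frame(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2))
  expect_equal(convex_hull_coverage(unit_sq, big_sq), 0.25)
  expect_equal(convex_hull_coverage(big_sq, big_sq), 1)

  set.seed(2)
  inner <- data.frame(x = runif(30, 0.5, 1.5), y = runif(30, 0.5, 1.5))
  expect_lte(convex_hull_coverage(inner, big_sq), 1)

  line <- data.frame(x = 1:5, y = 1:5)
  expect_error(convex_hull_coverage(line, big_sq), "non-collinear")
  expect_error(convex_hull_coverage(big_sq, line), "non-collinear")
})

test_that("coverage is invariant under joint rigid motions", {
  set.seed(3)
  a <- data.frame(x = runif(20), y = runif(20))
  b <- data.frame(x = runif(25, -1, 2), y = runif(25, -1, 2))
  base <- convex_hull_coverage(a, b)
  th <- 1.1; dx <- 5; dy <- -2
  rot <- function(d) data.frame(x = cos(th) * d$x - sin(th) * d$y + dx,
                                y = sin(th) * d$x + cos(th) * d$y + dy)
  expect_equal(convex_hull_coverage(rot(a), rot(b)), base,
               tolerance = 1e-12)
})

test_that("scenario assignment median-splits with upper-bin ties", {
  d <- tibble::tibble(
    species_id = paste0("s", 1:4),
    clark_evans = c(0.2, 0.4, 0.8, 1.0),
    coverage = c(0.9, 1.0, 0.2, 0.4))
  a <- assign_scenarios(d)
  expect_setequal(a$scenario,
                  c("clumped & high_coverage", "even & restricted"))
  expect_equal(sum(a$clump_bin == "clumped"), 2)
  expect_equal(sum(a$coverage_bin == "restricted"), 2)

  same <- tibble::tibble(species_id = paste0("s", 1:6),
                         clark_evans = 1, coverage = 1)
  a2 <- assign_scenarios(same)
  expect_true(all(a2$scenario == "even & high_coverage"))

  expect_error(assign_scenarios(d[1:3, ]), "at least 4")

  # bins partition any batch
  set.seed(9)
  big <- tibble::tibble(species_id = paste0("s", 1:101),
                        clark_evans = runif(101), coverage = runif(101))
  a3 <- assign_scenarios(big)
  expect_equal(sum(table(a3$scenario)), 101)
  expect_equal(sum(a3$clump_bin == "clumped"), 50)
  expect_equal(sum(a3$coverage_bin == "restricted"), 50)
})
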