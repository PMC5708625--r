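#' Generate a spatially heterogeneous reporting-rate layer
#'
#' Partitions the landscape into six contiguous regions (the Voronoi cells of
#' six uniform-random centres) and assigns each region an independent
#' Uniform(0, 1) reporting rate — the probability that an occurrence seeded
#' there is actually recorded.
#'
#' @param grid A [grid_spec()].
#' @param rng_seed Integer seed.
#' @param n_regions Number of regions (default 6).
#' @return An object of class `reporting_layer`: list with `grid`,
#'   `region_id` (per-cell integer), `rate` (per-cell probability),
#'   `region_rates` and `centres`.
#' @export
generate_reporting_layer <- function(grid, rng_seed, n_regions = 6) {
  stopifnot(inherits(grid, "grid_spec"))
  ext <- grid_extent(grid)
  withr::with_seed(rng_seed, {
    centres <- tibble::tibble(
      x = stats::runif(n_regions, ext["xmin"], ext["xmax"]),
      y = stats::runif(n_regions, ext["ymin"], ext["ymax"])
    )
    region_rates <- stats::runif(n_regions)
  })
  cc <- cell_centres(grid)
  d2 <- outer(cc$x, centres$x, `-`)^2 + outer(cc$y, centres$y, `-`)^2
  region_id <- max.col(-d2, ties.method = "first")
  region_id <- enforce_contiguity(region_id, grid, n_regions)
  structure(
    list(grid = grid, region_id = region_id,
         rate = region_rates[region_id],
         region_rates = region_rates, centres = centres),
    class = "reporting_layer"
  )
}

# Discretising convex Voronoi cells onto the grid can shear off 4-connected
# slivers; merge any minor fragment into the neighbouring region it touches
# most so the six regions stay contiguous.
enforce_contiguity <- function(region_id, grid, n_regions) {
  nr <- grid$n_rows; nc <- grid$n_cols
  m <- matrix(region_id, nr, nc, byrow = TRUE)
  repeat {
    changed <- FALSE
    for (r in seq_len(n_regions)) {
      cells <- which(m == r)
      if (length(cells) == 0) next
      comp <- integer(length(m))  # 0 = unvisited
      comp_id <- 0
      for (start in cells) {
        if (comp[start] > 0) next
        comp_id <- comp_id + 1
        queue <- start
        comp[start] <- comp_id
        while (length(queue)) {
          cur <- queue[length(queue)]
          queue <- queue[-length(queue)]
          ri <- (cur - 1) %% nr + 1; ci <- (cur - 1) %/% nr + 1
          for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
            ri2 <- ri + d[1]; ci2 <- ci + d[2]
            if (ri2 >= 1 && ri2 <= nr && ci2 >= 1 && ci2 <= nc) {
              nb <- (ci2 - 1) * nr + ri2
              if (m[nb] == r && comp[nb] == 0) {
                comp[nb] <- comp_id
                queue <- c(queue, nb)
              }
            }
          }
        }
      }
      if (comp_id > 1) {
        sizes <- tabulate(comp[cells], comp_id)
        main <- which.max(sizes)
        frag <- cells[comp[cells] != main]
        for (f in frag) {
          ri <- (f - 1) %% nr + 1; ci <- (f - 1) %/% nr + 1
          nbs <- c(if (ri > 1) m[ri - 1, ci], if (ri < nr) m[ri + 1, ci],
                   if (ci > 1) m[ri, ci - 1], if (ci < nc) m[ri, ci + 1])
          nbs <- nbs[nbs != r]
          if (length(nbs)) {
            m[ri, ci] <- as.integer(names(which.max(table(nbs))))
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  as.integer(t(m))
}

#' @export
print.reporting_layer <- function(x, ...) {
  cat(sprintf("<reporting_layer> %d regions, rates: %s\n",
              length(x$region_rates),
              paste(sprintf("%.2f", x$region_rates), collapse = " ")))
  invisible(x)
}

#' Draw uniform seed points for the sampling process
#'
#' A small random number of seed points — the foci that occurrence records
#' will cluster around — placed uniformly over the landscape.
#'
#' @param grid A [grid_spec()].
#' @param rng_seed Integer seed.
#' @param min_seeds,max_seeds Bounds of the uniform-integer seed count
#'   (defaults 5 and 20).
#' @return A tibble with columns `x`, `y`, `retained` (all `TRUE`; updated by
#'   [filter_seeds()]).
#' @export
draw_seed_points <- function(grid, rng_seed, min_seeds = 5, max_seeds = 20) {
  stopifnot(inherits(grid, "grid_spec"))
  if (min_seeds < 1 || max_seeds < min_seeds) {
    stop("need 1 <= min_seeds <= max_seeds", call. = FALSE)
  }
  ext <- grid_extent(grid)
  withr::with_seed(rng_seed, {
    k <- min_seeds + sample.int(max_seeds - min_seeds + 1L, 1L) - 1L
    tibble::tibble(
      x = stats::runif(k, ext["xmin"], ext["xmax"]),
      y = stats::runif(k, ext["ymin"], ext["ymax"]),
      retained = TRUE
    )
  })
}

#' Filter seed points through the reporting layer
#'
#' Each seed survives independently with the reporting rate of its cell. If
#' no seed survives, one uniformly chosen seed is force-retained so that a
#' sample always exists.
#'
#' @param seeds Tibble from [draw_seed_points()].
#' @param reporting A [generate_reporting_layer()] result.
#' @param rng_seed Integer seed.
#' @return The seeds tibble with `retained` updated.
#' @export
filter_seeds <- function(seeds, reporting, rng_seed) {
  stopifnot(inherits(reporting, "reporting_layer"))
  cells <- point_to_cell(reporting$grid, seeds$x, seeds$y)
  if (anyNA(cells)) stop("seed points fall outside the grid", call. = FALSE)
  withr::with_seed(rng_seed, {
    keep <- stats::runif(nrow(seeds)) < reporting$rate[cells]
    if (!any(keep)) keep[sample.int(nrow(seeds), 1)] <- TRUE
  })
  seeds$retained <- keep
  seeds
}

#' Clumping parameters for the secondary sampling process
#'
#' The clumping coefficient `c` is the mean of the Gaussian governing the
#' displacement distance (in cell units) of occurrence records from their
#' seed point; its standard deviation is fixed at `c / 5`. Small `c` gives
#' tight clusters, large `c` a diffuse spread.
#'
#' @param c Clumping coefficient in `[1, 50]`.
#' @return A list with `c` and `c_sd = c / 5`, class `clumping_params`.
#' @export
clumping_params <- function(c) {
  if (!is.numeric(c) || length(c) != 1 || c < 1 || c > 50) {
    stop("clumping coefficient must lie in [1, 50]", call. = FALSE)
  }
  structure(list(c = as.numeric(c), c_sd = as.numeric(c) / 5),
            class = "clumping_params")
}

#' Draw a clumped presence-only occurrence sample
#'
#' Repeatedly picks a retained seed uniformly at random, displaces it by an
#' absolute Gaussian distance (mean `clumping$c`, sd `c/5`; negative draws
#' reflected) in a uniform direction, and rejects candidates off the grid.
#' Occurrence records are records of the species, so in both modes a
#' candidate must fall on an occupied cell (noisy truth probability above
#' 0.5 — the same realised-occupancy rule the validation labels use). Under
#' `bias_mode = "biological"` a candidate is additionally accepted with
#' probability equal to the suitability at its cell, so report density
#' grades with abundance inside the range; under `"random"` sampling effort
#' is independent of suitability given occupancy.
#'
#' @param seeds Seed tibble (after [filter_seeds()]); at least one retained.
#' @param clumping A [clumping_params()] object.
#' @param truth A [predict_truth_surface()] result (used in biological mode).
#' @param bias_mode `"biological"` or `"random"`.
#' @param n_total Number of occurrence points, in `[25, 500]`.
#' @param rng_seed Integer seed.
#' @param max_attempts Candidate budget before aborting (default
#'   `1000 * n_total`), guarding against species with near-zero suitability
#'   everywhere reachable.
#' @return An object of class `occurrence_sample`: tibble of `x`, `y` with
#'   attributes `bias_mode`, `clumping`, `seed_set`.
#' @export
draw_clumped_samples <- function(seeds, clumping, truth, bias_mode, n_total,
                                 rng_seed, max_attempts = 1000 * n_total) {
  stopifnot(inherits(clumping, "clumping_params"),
            inherits(truth, "truth_surface"))
  bias_mode <- match.arg(bias_mode, c("biological", "random"))
  n_total <- as.integer(n_total)
  if (is.na(n_total) || n_total < 25L || n_total > 500L) {
    stop("`n_total` must lie in [25, 500]", call. = FALSE)
  }
  live <- seeds[seeds$retained, , drop = FALSE]
  if (nrow(live) == 0) stop("no retained seed points", call. = FALSE)
  grid <- truth$grid
  cs <- grid$cell_size

  withr::with_seed(rng_seed, {
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0
    while (length(xs) < n_total && attempts < max_attempts) {
      m <- min(4L * (n_total - length(xs)) + 32L, max_attempts - attempts)
      attempts <- attempts + m
      si <- sample.int(nrow(live), m, replace = TRUE)
      dist <- abs(stats::rnorm(m, clumping$c, clumping$c_sd)) * cs
      ang <- stats::runif(m, 0, 2 * pi)
      cx <- live$x[si] + dist * cos(ang)
      cy <- live$y[si] + dist * sin(ang)
      ok <- points_in_grid(grid, cx, cy)
      cells <- point_to_cell(grid, cx, cy)
      ok <- ok & !is.na(cells)
      ok[ok] <- truth$p_noisy[cells[ok]] > 0.5
      if (bias_mode == "biological") {
        ok[ok] <- stats::runif(sum(ok)) < truth$p_noisy[cells[ok]]
      }
      xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
    }
  })
  if (length(xs) < n_total) {
    stop(sprintf(
      "rejection sampling exhausted %d attempts with %d/%d points accepted",
      max_attempts, length(xs), n_total), call. = FALSE)
  }
  out <- tibble::tibble(x = xs[seq_len(n_total)], y = ys[seq_len(n_total)])
  attr(out, "bias_mode") <- bias_mode
  attr(out, "clumping") <- clumping
  attr(out, "seed_set") <- seeds
  class(out) <- c("occurrence_sample", class(out))
  out
}

#' @method autoplot occurrence_sample
#' @export
autoplot.occurrence_sample <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_raster(
      data = as_tibble.truth_surface(truth),
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$p_noisy)) +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1))
  }
  p + ggplot2::geom_point(
    data = tibble::as_tibble(object),
    ggplot2::aes(x = .data$x, y = .data$y),
    colour = "red", size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", fill = "P(presence)")
}
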