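#' Clark-Evans dispersion index of a point pattern
#'
#' Ratio of the observed mean nearest-neighbour distance to its expectation
#' under complete spatial randomness at the same intensity,
#' `1 / (2 * sqrt(n / study_area))`. Values below 1 indicate clumping, about
#' 1 randomness, above 1 regularity. The classical estimator is used, with
#' no edge correction and the full landscape as the reference window.
#'
#' @param points A data frame with `x`, `y` columns (>= 2 rows).
#' @param study_area Reference area in squared coordinate units (> 0);
#'   typically [grid_spec()] area via the internal grid helpers.
#' @return A single non-negative number.
#' @export
#' @examples
#' pts <- expand.grid(x = 1:10, y = 1:10)
#' clark_evans_index(pts, study_area = 100)  # regular lattice -> ~2
clark_evans_index <- function(points, study_area) {
  if (!is.data.frame(points) || nrow(points) < 2) {
    stop("need at least 2 points", call. = FALSE)
  }
  if (!is.numeric(study_area) || study_area <= 0) {
    stop("`study_area` must be > 0", call. = FALSE)
  }
  d <- as.matrix(stats::dist(cbind(points$x, points$y)))
  diag(d) <- Inf
  r_obs <- mean(apply(d, 1, min))
  r_exp <- 1 / (2 * sqrt(nrow(points) / study_area))
  r_obs / r_exp
}

# Shoelace polygon area of the convex hull of a point set.
hull_area <- function(points) {
  xy <- unique(cbind(points$x, points$y))
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Convex-hull coverage of a sample relative to the true range
#'
#' Area of the convex hull of the occurrence sample divided by the area of
#' the convex hull of the true-presence (label = 1) validation points — a
#' proxy for how much of the species' range of occurrence the sample spans.
#' Planar shoelace areas in squared cell units.
#'
#' @param sample_points Data frame with `x`, `y` (>= 3 non-collinear rows).
#' @param true_presence_points Data frame with `x`, `y` of the known range
#'   (>= 3 non-collinear rows), e.g. validation points with `label == 1`.
#' @return A single non-negative number (typically <= 1; can exceed 1 when
#'   the sample hull overshoots the range hull).
#' @export
convex_hull_coverage <- function(sample_points, true_presence_points) {
  a_s <- hull_area(sample_points)
  a_t <- hull_area(true_presence_points)
  if (a_s == 0 || a_t == 0) {
    stop("convex-hull coverage needs >= 3 non-collinear points in each set",
         call. = FALSE)
  }
  a_s / a_t
}

#' Compute sample diagnostics for one species
#'
#' @param sample An occurrence sample (data frame with `x`, `y`).
#' @param validation Validation tibble from [sample_validation_points()].
#' @param grid The [grid_spec()] (reference window for Clark-Evans).
#' @return A one-row tibble: `n_points`, `clark_evans`, `coverage`.
#' @export
sample_diagnostics <- function(sample, validation, grid) {
  tibble::tibble(
    n_points = nrow(sample),
    clark_evans = clark_evans_index(sample, grid_area(grid)),
    coverage = convex_hull_coverage(sample,
                                    validation[validation$label == 1, ])
  )
}

#' Assign clumping/coverage scenario bins by batch median splits
#'
#' Splits the batch at the median Clark-Evans index (below the median:
#' `clumped`, otherwise `even`) and the median coverage (below: `restricted`,
#' otherwise `high_coverage`); values equal to the median go to the upper
#' bin. The scenario is the cross of the two bins.
#'
#' @param diagnostics A data frame with columns `clark_evans` and `coverage`
#'   (>= 4 rows; one row per species).
#' @return The input with `clump_bin`, `coverage_bin` and `scenario` columns
#'   appended.
#' @export
assign_scenarios <- function(diagnostics) {
  if (!is.data.frame(diagnostics) || nrow(diagnostics) < 4) {
    stop("need at least 4 diagnostics rows to median-split", call. = FALSE)
  }
  med_ce <- stats::median(diagnostics$clark_evans)
  med_cv <- stats::median(diagnostics$coverage)
  dplyr::mutate(
    tibble::as_tibble(diagnostics),
    clump_bin = ifelse(.data$clark_evans < med_ce, "clumped", "even"),
    coverage_bin = ifelse(.data$coverage < med_cv, "restricted",
                          "high_coverage"),
    scenario = paste(.data$clump_bin, .data$coverage_bin, sep = " & ")
  )
}
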