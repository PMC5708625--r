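#' Generate pseudo-absence (background) points
#'
#' Background strategies follow the common presence-background conventions:
#' * `R`  — uniform-random cells across the landscape;
#' * `SW` — spatially weighted: cells drawn with probability proportional to
#'   a Gaussian kernel-density estimate of the presence points (bandwidth by
#'   Silverman's rule per axis), so the background shares the presences'
#'   spatial structure;
#' * `ST` — background as in `R` (the thinning of `ST` acts on presences via
#'   [thin_presences()], not on the background);
#' * `B`  — both: `SW` background, with presence thinning applied upstream.
#'
#' @param grid A [grid_spec()].
#' @param presences Data frame of presence `x`, `y` (used by `SW`/`B`).
#' @param strategy One of `"R"`, `"SW"`, `"ST"`, `"B"`.
#' @param n_background Number of background points (default 1000, >= 10).
#' @param rng_seed Integer seed.
#' @return A tibble of `x`, `y` (cell centres) with attributes `strategy`
#'   and `n_background`.
#' @export
generate_background <- function(grid, presences, strategy = "R",
                                n_background = 1000, rng_seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  strategy <- match.arg(strategy, c("R", "SW", "ST", "B"))
  n_background <- as.integer(n_background)
  if (is.na(n_background) || n_background < 10L) {
    stop("`n_background` must be >= 10", call. = FALSE)
  }
  cc <- cell_centres(grid)
  weighted <- strategy %in% c("SW", "B")
  if (weighted) {
    if (is.null(presences) || nrow(presences) < 2) {
      stop("SW/B background needs >= 2 presence points", call. = FALSE)
    }
    ext <- grid_extent(grid)
    bw <- c(silverman_bw(presences$x), silverman_bw(presences$y))
    kde <- MASS::kde2d(presences$x, presences$y, h = bw,
                       n = c(grid$n_cols, grid$n_rows),
                       lims = c(ext["xmin"] + grid$cell_size / 2,
                                ext["xmax"] - grid$cell_size / 2,
                                ext["ymin"] + grid$cell_size / 2,
                                ext["ymax"] - grid$cell_size / 2))
    # kde$z is n_cols x n_rows with x varying along rows: flatten row-major
    # by cell index (x fastest) = as.numeric of the matrix itself.
    w <- pmax(as.numeric(kde$z), 0)
    if (sum(w) <= 0) w <- rep(1, nrow(cc))
  } else {
    w <- rep(1, nrow(cc))
  }
  cells <- withr::with_seed(rng_seed,
    sample.int(nrow(cc), n_background, replace = TRUE, prob = w))
  out <- tibble::tibble(x = cc$x[cells], y = cc$y[cells])
  attr(out, "strategy") <- strategy
  attr(out, "n_background") <- n_background
  out
}

# Silverman's rule-of-thumb bandwidth for one axis (guarding degenerate IQR).
silverman_bw <- function(v) {
  s <- stats::sd(v)
  iqr <- stats::IQR(v) / 1.349
  spread <- min(s, iqr)
  if (!is.finite(spread) || spread <= 0) spread <- max(s, 1e-6)
  # kde2d's h is the full kernel width (sd * 4 in MASS convention uses h/4)
  4 * 0.9 * spread * length(v)^(-1 / 5)
}

#' Spatially thin presence points
#'
#' Greedy thinning in input order: a point is kept iff it lies at least
#' `min_distance` from every point already kept, so the output has all
#' pairwise distances >= `min_distance`.
#'
#' @param presences Data frame with `x`, `y`.
#' @param min_distance Minimum pairwise distance (cell units, > 0;
#'   default 2).
#' @return The thinned subset, same columns.
#' @export
thin_presences <- function(presences, min_distance = 2) {
  if (!is.numeric(min_distance) || min_distance <= 0) {
    stop("`min_distance` must be > 0", call. = FALSE)
  }
  n <- nrow(presences)
  if (n == 0) return(presences)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kx) == 0 ||
        min((presences$x[i] - kx)^2 + (presences$y[i] - ky)^2) >=
          min_distance^2) {
      keep[i] <- TRUE
      kx <- c(kx, presences$x[i]); ky <- c(ky, presences$y[i])
    }
  }
  presences[keep, , drop = FALSE]
}
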