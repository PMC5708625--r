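#' Generate synthetic environmental covariate layers
#'
#' Builds `n_cov` standardized surfaces that emulate broad-scale bio-climatic
#' layers (temperature, rainfall, ...). Each layer is constructed by
#' projecting cell centres onto a random axis (left-right, top-bottom or
#' diagonal), mapping the projected position linearly onto a random window of
#' the quantile axis of a random Gaussian, and evaluating the Gaussian
#' density there. A window confined to one tail yields a monotone gradient;
#' a window straddling the mode yields a humped surface. Layers are z-scored
#' so every layer has mean 0 and standard deviation 1 across cells.
#'
#' @param grid A [grid_spec()].
#' @param n_cov Number of covariate layers (default 5).
#' @param rng_seed Integer seed; the stack is a pure function of it.
#'
#' @return An object of class `covariate_stack`: list with `grid`, `values`
#'   (cells x layers matrix, columns `cov1..covk`) and `layer_meta` (tibble
#'   with the generator draw per layer).
#' @export
#' @examples
#' cs <- generate_covariates(grid_spec(12, 10), n_cov = 3, rng_seed = 1)
#' colMeans(cs$values)  # ~0
generate_covariates <- function(grid, n_cov = 5, rng_seed) {
  stopifnot(inherits(grid, "grid_spec"))
  n_cov <- as.integer(n_cov)
  if (is.na(n_cov) || n_cov < 1L) stop("`n_cov` must be >= 1", call. = FALSE)
  withr::with_seed(rng_seed, {
    meta <- vector("list", n_cov)
    vals <- matrix(NA_real_, n_cells(grid), n_cov)
    for (k in seq_len(n_cov)) {
      orientation <- sample(c("left-right", "top-bottom", "diagonal"), 1)
      angle <- switch(orientation,
        "left-right" = 0,
        "top-bottom" = pi / 2,
        "diagonal"   = sample(c(pi / 4, 3 * pi / 4), 1)
      )
      mu <- stats::runif(1, -1, 1)
      sigma <- stats::runif(1, 0.5, 2)
      q_lo <- stats::runif(1, 0.01, 0.60)
      q_hi <- min(q_lo + stats::runif(1, 0.20, 0.90), 0.99)
      flip <- sample(c(1, -1), 1)
      vals[, k] <- layer_field(grid, angle, q_lo, q_hi, mu, sigma, flip)
      meta[[k]] <- tibble::tibble(
        layer = k,
        kind = if (q_lo >= 0.5 || q_hi <= 0.5) "gradient" else "hump",
        orientation = orientation, angle = angle,
        mu = mu, sigma = sigma, q_lo = q_lo, q_hi = q_hi, flip = flip
      )
    }
    colnames(vals) <- paste0("cov", seq_len(n_cov))
    structure(
      list(grid = grid, values = vals, layer_meta = dplyr::bind_rows(meta)),
      class = "covariate_stack"
    )
  })
}

# Deterministic layer kernel: projected position -> Gaussian density over a
# quantile window, z-scored. Exposed internally so tests can force windows.
layer_field <- function(grid, angle, q_lo, q_hi, mu = 0, sigma = 1, flip = 1) {
  cc <- cell_centres(grid)
  ext <- grid_extent(grid)
  xn <- (cc$x - ext["xmin"]) / (ext["xmax"] - ext["xmin"])
  yn <- (cc$y - ext["ymin"]) / (ext["ymax"] - ext["ymin"])
  t <- cos(angle) * xn + sin(angle) * yn
  t <- (t - min(t)) / (max(t) - min(t))
  q <- q_lo + t * (q_hi - q_lo)
  v <- flip * stats::dnorm(stats::qnorm(q, mu, sigma), mu, sigma)
  as.numeric(scale(v))
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layers on a %d x %d grid\n",
              ncol(x$values), x$grid$n_cols, x$grid$n_rows))
  print(x$layer_meta[, c("layer", "kind", "orientation")])
  invisible(x)
}

#' @method as_tibble covariate_stack
#' @export
as_tibble.covariate_stack <- function(x, ...) {
  dplyr::bind_cols(cell_centres(x$grid)[, c("cell", "x", "y")],
                   tibble::as_tibble(x$values))
}

#' Plot covariate layers as raster tiles
#' @param object A `covariate_stack`.
#' @param ... Unused.
#' @return A ggplot object, one facet per layer.
#' @method autoplot covariate_stack
#' @export
autoplot.covariate_stack <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble.covariate_stack(object),
                            dplyr::starts_with("cov"),
                            names_to = "layer", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", fill = "z")
}
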