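#' Design specification for regression-type engines
#'
#' @param covariate_subset Integer indices of the covariate layers to use.
#' @param include_squares Add squared terms? (default `TRUE`)
#' @param include_interactions Add pairwise products? (default `FALSE`)
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(covariate_subset = 1:5, include_squares = TRUE,
                        include_interactions = FALSE) {
  covariate_subset <- as.integer(covariate_subset)
  if (length(covariate_subset) == 0 || anyNA(covariate_subset) ||
      any(covariate_subset < 1)) {
    stop("`covariate_subset` must be a non-empty set of positive indices",
         call. = FALSE)
  }
  structure(list(covariate_subset = sort(unique(covariate_subset)),
                 include_squares = isTRUE(include_squares),
                 include_interactions = isTRUE(include_interactions)),
            class = "design_spec")
}

design_terms <- function(spec) {
  idx <- spec$covariate_subset
  out <- tibble::tibble(kind = "linear", i = idx, j = NA_integer_)
  if (spec$include_squares) {
    out <- dplyr::bind_rows(out,
      tibble::tibble(kind = "square", i = idx, j = NA_integer_))
  }
  if (spec$include_interactions && length(idx) >= 2) {
    ij <- utils::combn(idx, 2)
    out <- dplyr::bind_rows(out,
      tibble::tibble(kind = "interaction", i = ij[1, ], j = ij[2, ]))
  }
  out$term <- term_label(out)
  out
}

#' Build a standardized predictor matrix at point locations
#'
#' Extracts covariate values at each point's containing cell, expands them
#' per the design spec (linear, square, pairwise product columns), and
#' standardizes each column by the training points' mean and standard
#' deviation. The transform is stored so the identical mapping can be
#' applied to every grid cell at prediction time.
#'
#' @param covariates A [generate_covariates()] stack.
#' @param points Data frame with `x`, `y` inside the grid.
#' @param spec A [design_spec()].
#' @return An object of class `sdm_design`: list with `X` (matrix), `spec`,
#'   `terms`, `center`, `scale`.
#' @export
build_design <- function(covariates, points, spec = design_spec()) {
  stopifnot(inherits(covariates, "covariate_stack"),
            inherits(spec, "design_spec"))
  if (max(spec$covariate_subset) > ncol(covariates$values)) {
    stop("`covariate_subset` indexes a missing layer", call. = FALSE)
  }
  cells <- point_to_cell(covariates$grid, points$x, points$y)
  if (anyNA(cells)) stop("points fall outside the grid", call. = FALSE)
  terms <- design_terms(spec)
  X <- eval_terms(covariates$values[cells, , drop = FALSE], terms)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  X <- sweep(sweep(X, 2, center), 2, scale, "/")
  structure(list(X = X, spec = spec, terms = terms,
                 center = center, scale = scale),
            class = "sdm_design")
}

# The same standardized expansion evaluated at every grid cell.
design_matrix_cells <- function(design, covariates) {
  X <- eval_terms(covariates$values, design$terms)
  sweep(sweep(X, 2, design$center), 2, design$scale, "/")
}
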