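new_fitted_sdm <- function(method, prediction, fit_info, config,
                           design = NULL, predictor = NULL) {
  stopifnot(all(is.finite(prediction)),
            all(prediction >= 0 & prediction <= 1))
  structure(
    list(method = method, prediction = prediction, fit_info = fit_info,
         config = config, design = design, predictor = predictor),
    class = "fitted_sdm"
  )
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("<fitted_sdm> method %s, %d prediction cells\n",
              x$method, length(x$prediction)))
  invisible(x)
}

#' Per-cell prediction surface of a fitted engine
#'
#' Re-applies the stored feature transform and fitted model to every grid
#' cell of a covariate stack. For the stack the model was trained on this
#' reproduces the cached `prediction`; passing a different (but structurally
#' compatible) stack re-scores it.
#'
#' @param model A `fitted_sdm`.
#' @param covariates A [generate_covariates()] stack with at least as many
#'   layers as the model's design used.
#' @return Numeric vector of per-cell scores in `[0, 1]`.
#' @export
predict_surface <- function(model, covariates) {
  stopifnot(inherits(model, "fitted_sdm"),
            inherits(covariates, "covariate_stack"))
  if (!is.null(model$predictor)) return(model$predictor(covariates))
  design <- model$design
  if (is.null(design)) return(model$prediction)
  if (max(design$spec$covariate_subset) > ncol(covariates$values)) {
    stop("covariate stack lacks layers required by the model",
         call. = FALSE)
  }
  Xc <- cbind(1, design_matrix_cells(design, covariates))
  stats::plogis(as.numeric(Xc %*% model$fit_info$beta))
}

#' Tidy the parameters of a fitted engine
#'
#' For the Bayesian GLMs: posterior mode and sd per coefficient. For the
#' MaxEnt-style model: non-zero feature weights. For boosted trees: gain
#' importance per predictor.
#'
#' @param x A `fitted_sdm`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fitted_sdm
#' @export
tidy.fitted_sdm <- function(x, ...) {
  fi <- x$fit_info
  if (!is.null(fi$beta) && !is.null(fi$beta_sd)) {
    tibble::tibble(term = names(fi$beta), estimate = unname(fi$beta),
                   std.error = unname(fi$beta_sd))
  } else if (!is.null(fi$weights)) {
    tibble::tibble(term = names(fi$weights), estimate = unname(fi$weights))
  } else if (!is.null(fi$importance)) {
    tibble::as_tibble(fi$importance)
  } else {
    tibble::tibble(term = character(), estimate = numeric())
  }
}

#' One-row summary of a fitted engine
#' @param x A `fitted_sdm`.
#' @param ... Unused.
#' @return A one-row tibble: method, training size, convergence info.
#' @method glance fitted_sdm
#' @export
glance.fitted_sdm <- function(x, ...) {
  fi <- x$fit_info
  tibble::tibble(
    method = x$method,
    n_train = fi$n_train %||% NA_integer_,
    iterations = fi$iterations %||% NA_integer_,
    log_posterior = fi$log_posterior %||% NA_real_,
    n_nonzero = fi$n_nonzero %||% NA_integer_
  )
}

#' Plot a fitted prediction surface
#' @param object A `fitted_sdm`.
#' @param grid The [grid_spec()] the prediction lives on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fitted_sdm
#' @export
autoplot.fitted_sdm <- function(object, grid, ...) {
  df <- dplyr::bind_cols(cell_centres(grid)[, c("x", "y")],
                         tibble::tibble(score = object$prediction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$method, fill = "score",
                  x = "x (deg)", y = "y (deg)")
}
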