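#' Enumerate the candidate term pool for virtual species models
#'
#' The generating regression for a virtual species draws its terms from a
#' pool of all linear and square terms per covariate plus all first-order
#' pairwise interactions: `n + n + n(n-1)/2` terms for `n` covariates
#' (20 for the default 5 covariates).
#'
#' @param n_cov Number of covariate layers.
#' @return A tibble with columns `term` (label), `kind`
#'   (`linear`/`square`/`interaction`), `i`, `j` (layer indices; `j` is `NA`
#'   except for interactions, where `i < j`).
#' @export
#' @examples
#' nrow(enumerate_term_pool(5))  # 20
enumerate_term_pool <- function(n_cov) {
  n_cov <- as.integer(n_cov)
  if (is.na(n_cov) || n_cov < 1L) stop("`n_cov` must be >= 1", call. = FALSE)
  lin <- tibble::tibble(kind = "linear", i = seq_len(n_cov), j = NA_integer_)
  sqr <- tibble::tibble(kind = "square", i = seq_len(n_cov), j = NA_integer_)
  if (n_cov >= 2) {
    ij <- utils::combn(n_cov, 2)
    int <- tibble::tibble(kind = "interaction", i = ij[1, ], j = ij[2, ])
  } else {
    int <- tibble::tibble(kind = character(), i = integer(), j = integer())
  }
  pool <- dplyr::bind_rows(lin, sqr, int)
  pool$term <- term_label(pool)
  pool[, c("term", "kind", "i", "j")]
}

term_label <- function(terms) {
  ifelse(terms$kind == "linear", paste0("cov", terms$i),
    ifelse(terms$kind == "square", paste0("cov", terms$i, "^2"),
      paste0("cov", terms$i, ":cov", terms$j)))
}

# Evaluate a tibble of terms over a cells-x-layers value matrix.
eval_terms <- function(values, terms) {
  bad <- terms$i > ncol(values) |
    (!is.na(terms$j) & terms$j > ncol(values))
  if (any(bad)) {
    stop("term references a covariate layer outside the stack", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(values), nrow(terms))
  for (k in seq_len(nrow(terms))) {
    out[, k] <- switch(terms$kind[k],
      linear = values[, terms$i[k]],
      square = values[, terms$i[k]]^2,
      interaction = values[, terms$i[k]] * values[, terms$j[k]],
      stop("unknown term kind: ", terms$kind[k], call. = FALSE)
    )
  }
  colnames(out) <- terms$term
  out
}

#' Draw a random virtual species model
#'
#' Selects a uniform-random number of terms (at least one, without
#' replacement) from the pool and draws each coefficient and the intercept
#' from a zero-mean Gaussian.
#'
#' @param pool Term pool tibble from [enumerate_term_pool()].
#' @param rng_seed Integer seed.
#' @param coef_sd Standard deviation of the coefficient/intercept draws
#'   (default 1; covariates are standardized, so this sets logit-scale
#'   effect sizes).
#' @return An object of class `species_model`: list with `terms` (tibble
#'   with a `coefficient` column) and `intercept`.
#' @export
draw_species_model <- function(pool, rng_seed, coef_sd = 1) {
  if (!is.data.frame(pool) || nrow(pool) == 0) {
    stop("`pool` must be a non-empty term pool", call. = FALSE)
  }
  if (!is.numeric(coef_sd) || coef_sd <= 0) {
    stop("`coef_sd` must be > 0", call. = FALSE)
  }
  withr::with_seed(rng_seed, {
    k <- sample.int(nrow(pool), 1)
    sel <- sort(sample.int(nrow(pool), k))
    terms <- pool[sel, , drop = FALSE]
    terms$coefficient <- stats::rnorm(k, 0, coef_sd)
    structure(list(terms = terms, intercept = stats::rnorm(1, 0, coef_sd)),
              class = "species_model")
  })
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf("<species_model> %d terms, intercept %.3f\n",
              nrow(x$terms), x$intercept))
  print(x$terms[, c("term", "coefficient")])
  invisible(x)
}

#' @method tidy species_model
#' @export
tidy.species_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", kind = "intercept",
                   coefficient = x$intercept),
    x$terms[, c("term", "kind", "coefficient")]
  )
}

#' Predict the true presence-probability surface of a species
#'
#' Applies the generating regression to the covariate stack through the
#' inverse logit and adds independent per-cell Gaussian noise on the logit
#' scale, standing in for unmeasured environmental variation.
#'
#' @param model A [draw_species_model()] result.
#' @param covariates A [generate_covariates()] stack.
#' @param noise_sd Logit-scale noise standard deviation (>= 0, default 0.25).
#' @param rng_seed Integer seed for the noise draw.
#' @return An object of class `truth_surface`: list with `grid`, `p_clean`,
#'   `p_noisy` (per-cell probabilities), `noise_sd` and `species_model`.
#' @export
predict_truth_surface <- function(model, covariates, noise_sd = 0.25,
                                  rng_seed = 1) {
  stopifnot(inherits(model, "species_model"),
            inherits(covariates, "covariate_stack"))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  tm <- eval_terms(covariates$values, model$terms)
  eta <- model$intercept + as.numeric(tm %*% model$terms$coefficient)
  p_clean <- stats::plogis(eta)
  if (noise_sd > 0) {
    eps <- withr::with_seed(rng_seed, stats::rnorm(length(eta), 0, noise_sd))
    p_noisy <- stats::plogis(eta + eps)
  } else {
    p_noisy <- p_clean
  }
  structure(
    list(grid = covariates$grid, p_clean = p_clean, p_noisy = p_noisy,
         noise_sd = noise_sd, species_model = model),
    class = "truth_surface"
  )
}

#' @export
print.truth_surface <- function(x, ...) {
  cat(sprintf(
    "<truth_surface> %d cells, prevalence (noisy) %.3f, noise_sd %.3g\n",
    length(x$p_noisy), mean(x$p_noisy), x$noise_sd))
  invisible(x)
}

#' @method as_tibble truth_surface
#' @export
as_tibble.truth_surface <- function(x, ...) {
  dplyr::bind_cols(cell_centres(x$grid)[, c("cell", "x", "y")],
                   tibble::tibble(p_clean = x$p_clean, p_noisy = x$p_noisy))
}

#' Plot a true presence-probability surface
#' @param object A `truth_surface`.
#' @param which `"p_noisy"` (default) or `"p_clean"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot truth_surface
#' @export
autoplot.truth_surface <- function(object, which = "p_noisy", ...) {
  df <- as_tibble.truth_surface(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[which]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", fill = "P(presence)")
}

#' Sample a validation set of true presences and absences
#'
#' Draws `n` distinct cells uniformly at random and labels each with its
#' realised occupancy. Under the default `label_rule = "threshold"` a cell
#' is present iff its noisy truth probability exceeds 0.5 — the noisy
#' surface is treated as the realised (largely deterministic) true state,
#' which keeps the benchmark's AUC ceiling near 1 so that scores reflect
#' method error rather than irreducible label noise. `"bernoulli"` instead
#' draws each label from the cell's probability.
#'
#' @param truth A [predict_truth_surface()] result.
#' @param n Number of validation points (default 1000).
#' @param rng_seed Integer seed.
#' @param label_rule `"threshold"` (default) or `"bernoulli"`.
#' @return A tibble with columns `cell`, `x`, `y`, `label` (0/1) and
#'   attribute `prevalence`. Callers should reject species whose prevalence
#'   falls outside `[0.05, 0.95]` (see [simulate_species()]): AUC is
#'   unstable when one class is nearly absent.
#' @export
sample_validation_points <- function(truth, n = 1000, rng_seed = 1,
                                     label_rule = c("threshold",
                                                    "bernoulli")) {
  stopifnot(inherits(truth, "truth_surface"))
  label_rule <- match.arg(label_rule)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (n > n_cells(truth$grid)) {
    stop("`n` exceeds the number of grid cells", call. = FALSE)
  }
  withr::with_seed(rng_seed, {
    cells <- sample.int(n_cells(truth$grid), n, replace = FALSE)
    labels <- if (label_rule == "threshold") {
      as.integer(truth$p_noisy[cells] > 0.5)
    } else {
      stats::rbinom(n, 1, truth$p_noisy[cells])
    }
  })
  cc <- cell_centres(truth$grid)
  out <- tibble::tibble(cell = cells, x = cc$x[cells], y = cc$y[cells],
                        label = labels)
  attr(out, "prevalence") <- mean(labels)
  out
}
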