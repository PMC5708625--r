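#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed as the normalised Mann-Whitney statistic over all
#' presence-absence pairs: concordant pairs count 1, tied scores 0.5,
#' equivalent to the rank formula used here. Constant scores therefore give
#' exactly 0.5 and perfect separation 1.
#'
#' @param scores Numeric predicted scores.
#' @param labels Binary labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auc(c(0.9, 0.8, 0.4), c(1, 0, 1))  # 0.5
compute_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` differ in length", call. = FALSE)
  }
  check_two_classes(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score fitted engines against a validation set
#'
#' Reads each engine's prediction surface at the validation point cells and
#' computes the AUC against the validation labels.
#'
#' @param models Named list of `fitted_sdm` objects (names become the
#'   `method` column; unnamed lists fall back to each model's own method).
#' @param validation Tibble from [sample_validation_points()].
#' @param species_id Optional identifier carried into the result.
#' @return A tibble: `species_id`, `method`, `auc`.
#' @export
evaluate_species <- function(models, validation, species_id = NA) {
  if (inherits(models, "fitted_sdm")) models <- list(models)
  nm <- names(models) %||% vapply(models, `[[`, "", "method")
  if (is.null(names(models))) names(models) <- nm
  purrr::imap_dfr(models, function(m, name) {
    scores <- m$prediction[validation$cell]
    tibble::tibble(species_id = species_id,
                   method = if (nzchar(name)) name else m$method,
                   auc = compute_auc(scores, validation$label))
  })
}

#' Summarise AUC by method, scenario and bias process
#'
#' Mean AUC with a normal-approximation 95% confidence interval
#' (`mean +/- 1.96 sd/sqrt(n)`) over species in each
#' method x scenario x bias-mode cell. Single-species cells report a
#' collapsed interval with a warning.
#'
#' @param results Tibble of per-species AUCs (`species_id`, `method`, `auc`).
#' @param assignments Tibble with `species_id`, `scenario` (and optionally
#'   `bias_mode`) from [assign_scenarios()].
#' @return A tibble: `method`, `scenario`, `bias_mode`, `n_species`,
#'   `mean_auc`, `ci_low`, `ci_high`, of class `scenario_summary`.
#' @export
summarize_by_scenario <- function(results, assignments) {
  join_cols <- intersect(c("species_id"), names(assignments))
  df <- dplyr::inner_join(results, assignments, by = join_cols)
  if (!"bias_mode" %in% names(df)) df$bias_mode <- NA_character_
  if (nrow(df) < nrow(results)) {
    warning("some AUC results had no scenario assignment and were dropped")
  }
  out <- df |>
    dplyr::group_by(.data$method, .data$scenario, .data$bias_mode) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species_id),
      mean_auc = mean(.data$auc),
      sd_auc = stats::sd(.data$auc),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      half = ifelse(.data$n_species > 1,
                    1.96 * .data$sd_auc / sqrt(.data$n_species), 0),
      ci_low = .data$mean_auc - .data$half,
      ci_high = .data$mean_auc + .data$half
    ) |>
    dplyr::select(-"half", -"sd_auc")
  if (any(out$n_species == 1)) {
    warning("single-species groups report a collapsed confidence interval")
  }
  class(out) <- c("scenario_summary", class(out))
  out
}

#' Plot scenario summaries as mean AUC with confidence whiskers
#' @param object A [summarize_by_scenario()] result.
#' @param ... Unused.
#' @return A ggplot object (points + CI whiskers, facetted by scenario).
#' @method autoplot scenario_summary
#' @export
autoplot.scenario_summary <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$method, y = .data$mean_auc,
                 colour = .data$bias_mode)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "mean AUC", colour = "bias process") +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' Rank methods within scenario cells and count top-2 membership
#'
#' Ranks methods by mean AUC within each scenario x bias-mode cell (ties
#' share the better rank, so two methods tied at second both count as
#' top 2) and tallies, per method, the number of cells where it ranks in the
#' top 2.
#'
#' @param summaries A [summarize_by_scenario()] result.
#' @return A list with `rankings` (per-cell tibble with `rank` and `top2`)
#'   and `top2_counts` (per-method tibble).
#' @export
rank_methods <- function(summaries) {
  rk <- summaries |>
    dplyr::group_by(.data$scenario, .data$bias_mode) |>
    dplyr::mutate(rank = rank(-.data$mean_auc, ties.method = "min"),
                  top2 = .data$rank <= 2) |>
    dplyr::ungroup()
  counts <- rk |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(top2_cells = sum(.data$top2),
                     n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$top2_cells))
  list(rankings = rk, top2_counts = counts)
}
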