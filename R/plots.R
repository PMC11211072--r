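# ggplot2 views of the main result types.

#' Plot an ROI effect map
#'
#' Signed standardized effects per ROI, FDR-significant regions
#' highlighted.
#'
#' @param object An `effect_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot effect_map
#' @export
autoplot.effect_map <- function(object, ...) {
  df <- dplyr::mutate(object, idx = seq_len(nrow(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$effect_d,
                                   colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "ROI", y = "Cohen's d (case - control)",
                  colour = sprintf("q < %.2g", 0.05),
                  title = paste(attr(object, "contrast"), collapse = " vs ")) +
    ggplot2::theme_minimal()
}

#' Plot dimension-selection stability
#'
#' Mean pairwise ARI of resampled assignments per candidate k; the chosen
#' k is marked.
#'
#' @param object A `model_selection_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot model_selection_report
#' @export
autoplot.model_selection_report <- function(object, ...) {
  ggplot2::ggplot(object$stability,
                  ggplot2::aes(x = .data$k, y = .data$stability_ari)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 3) +
    ggplot2::geom_hline(yintercept = object$reliable_min, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "number of dimensions k", y = "stability ARI") +
    ggplot2::theme_minimal()
}

#' Forest plot of an interaction fit
#'
#' Coefficients with 95% confidence intervals; interaction terms
#' highlighted.
#'
#' @param object An `interaction_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot interaction_fit
#' @export
autoplot.interaction_fit <- function(object, ...) {
  df <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   colour = .data$interaction)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Mean percentage change by dimension and treatment arm
#'
#' The bar chart behind the interaction analysis: cell means of the
#' percentage HAM-D reduction.
#'
#' @param records Outcome tibble with `pct_change`, `arm` and a dimension
#'   column (`dimension` or `true_subtype`).
#' @param dimension_col Dimension column name.
#' @return A ggplot.
#' @export
plot_cell_means <- function(records, dimension_col = NULL) {
  dimension_col <- dimension_col %||%
    if ("dimension" %in% names(records)) "dimension" else "true_subtype"
  df <- dplyr::summarise(
    dplyr::group_by(records, dim = paste0("D", .data[[dimension_col]]),
                    .data$arm),
    mean_pct = mean(.data$pct_change), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim, y = .data$mean_pct,
                                   fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean % reduction in HAM-D",
                  fill = "arm") +
    ggplot2::theme_minimal()
}
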