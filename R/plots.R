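#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat-map of the strategy x algorithm x topic-count accuracy grid
#'
#' @param object A [heatmap_table()] result.
#' @param ... Unused.
#' @return A ggplot: topic count against algorithm, faceted by
#'   strategy, tile fill = mean cross-validated accuracy
#'   (demographics-only strategies appear as a single `k = none`
#'   column).
#' @method autoplot sdoh_heatmap
#' @export
autoplot.sdoh_heatmap <- function(object, ...) {
  df <- dplyr::mutate(object,
    k_label = ifelse(is.na(.data$k), "none", as.character(.data$k))
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$k_label, levels = unique(.data$k_label)),
    y = .data$algorithm, fill = .data$mean_accuracy
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$strategy),
      scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "#F7F7F7", high = "#B2182B",
      midpoint = max(df$mean_accuracy, na.rm = TRUE) / 2,
      limits = c(0, NA), name = "accuracy"
    ) +
    ggplot2::labs(x = "LDA topics (k)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the composition of a confusion-matrix prediction row
#'
#' @param cs A [confusion_summary()] or named count vector.
#' @param predicted_class Row to plot.
#' @return A ggplot bar chart of true-class shares within the row.
#' @export
plot_row_composition <- function(cs, predicted_class) {
  comp <- row_composition(cs, predicted_class)
  ggplot2::ggplot(comp, ggplot2::aes(
    x = stats::reorder(.data$class, .data$count),
    y = .data$percent
  )) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = paste0("Predictions labelled '", predicted_class, "'"),
      x = "true class", y = "% of row"
    ) +
    ggplot2::theme_minimal()
}

#' Plot accumulated per-class correct/incorrect predictions
#'
#' @param object A `perclass_report`.
#' @param ... Unused.
#' @return A ggplot stacked bar chart per class.
#' @method autoplot perclass_report
#' @export
autoplot.perclass_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$report, c("correct", "incorrect"),
    names_to = "outcome", values_to = "n"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$class, -.data$n), y = .data$n,
    fill = .data$outcome
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      correct = "#1B7837", incorrect = "#762A83"
    )) +
    ggplot2::labs(x = NULL, y = "accumulated predictions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
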