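#' Plot an incremental feature selection curve
#'
#' MCC (and optionally the other metrics) against the number of top-ranked
#' features used; the selected optimal prefix is marked.
#'
#' @param object A `pyr_ifs_curve` from [run_ifs()].
#' @param metrics Which metric columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pyr_ifs_curve <- function(object, metrics = "mcc", ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "k", dplyr::all_of(metrics)),
    -"k", names_to = "metric", values_to = "value")
  k_opt <- select_optimal(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = k_opt, linetype = "dashed") +
    ggplot2::labs(x = "number of top-ranked features",
                  y = "cross-validated value",
                  title = sprintf("Incremental feature selection (optimal k = %d)",
                                  k_opt)) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `pyr_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pyr_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.4f)", roc_auc(object))) +
    ggplot2::theme_minimal()
}

#' Plot a position-specific frequency table
#'
#' Heatmap of symbol frequencies by window offset, the tabular counterpart of
#' a sequence logo for the neighborhood of pyruvoyl serines.
#'
#' @param freq_table Tibble from [fit_frequency_table()].
#' @param min_freq Hide cells below this frequency.
#' @return A ggplot object.
#' @export
plot_frequency_table <- function(freq_table, min_freq = 0) {
  d <- dplyr::filter(freq_table, .data$freq >= min_freq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$symbol,
                                  fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "window offset", y = "symbol",
                  fill = "frequency") +
    ggplot2::theme_minimal()
}
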