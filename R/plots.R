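# ggplot2 visualizations for the main result types.

#' Plot a saliency map or averaged map as a heatmap
#'
#' @param object A `saliency_map` (or any numeric matrix via
#'   [plot_map_matrix()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saliency_map <- function(object, ...) {
  plot_map_matrix(unclass(object), legend = "saliency")
}

#' @rdname autoplot.saliency_map
#' @param m A numeric matrix (row = 5' position of the ordered pair).
#' @param legend Fill legend title.
#' @export
plot_map_matrix <- function(m, legend = "value") {
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[as.matrix(df)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = legend) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position j (5'→3')", y = "position i (5'→3')") +
    ggplot2::theme_minimal()
}

#' Histogram of matched vs shuffled overlap distributions
#'
#' @param object An `overlap_result` from [matched_vs_shuffled()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_result <- function(object, bins = 30, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent_overlap,
                                   fill = .data$assignment)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "% overlap with reference structure", y = "sequences",
                  subtitle = paste("rank-sum p =",
                                   format.pval(object$p_value))) +
    ggplot2::theme_minimal()
}

#' Per-fold metric plot for a cross-validated evaluation
#'
#' @param object A `toehold_eval` from [train_and_evaluate()].
#' @param ... Unused.
#' @return A ggplot (boxplot of per-fold metric values).
#' @export
autoplot.toehold_eval <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$output, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(title = paste(object$spec$family, object$spec$mode),
                  x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}

#' Kinetic folding trajectory plot
#'
#' @param object A `fold_trajectory`.
#' @param ... Unused.
#' @return A ggplot (energy step function over time).
#' @export
autoplot.fold_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$energy)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$mfe_energy, linetype = "dashed") +
    ggplot2::labs(x = "time (a.u.)", y = "energy (score units)") +
    ggplot2::theme_minimal()
}
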