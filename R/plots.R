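# ggplot2 conveniences. Plots are presentation sugar; the tested surface is
# the tibbles they are drawn from.

#' Plot performance-vs-k curves
#'
#' Mean metric with a +/- 1 SD ribbon against the feature subset size, one
#' colour per model.
#'
#' @param object a `gait_topk_sweep`.
#' @param metric metric to plot (default `"auc_roc"`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gait_topk_sweep <- function(object, metric = "auc_roc", ...) {
  curves <- aggregate_curves(object) |>
    dplyr::filter(.data$metric == !!metric)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$k, y = .data$mean,
                                       colour = .data$model,
                                       fill = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of selected features (k)", y = metric,
                  title = sprintf("%s vs feature subset size (%s)",
                                  metric, object$outcome)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of feature-selection frequency
#'
#' @param freq output of [selection_frequency()].
#' @param top_n how many features to show (default 20).
#' @return A ggplot object.
#' @export
plot_selection_frequency <- function(freq, top_n = 20L) {
  top <- utils::head(freq, top_n)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$frequency,
                                    y = stats::reorder(.data$feature,
                                                       .data$frequency))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "selection frequency across folds", y = NULL) +
    ggplot2::theme_minimal()
}

#' Ankle-distance signal with detected minima and the second cycle
#'
#' Diagnostic plot of the cycle segmentation for one recording.
#'
#' @param seq a [pose_sequence()].
#' @param ... passed to [extract_second_cycle()].
#' @return A ggplot object.
#' @export
plot_cycle_segmentation <- function(seq, ...) {
  sig <- ankle_distance(seq)
  seg <- extract_second_cycle(seq, ...)
  p <- ggplot2::ggplot(sig, ggplot2::aes(x = .data$frame, y = .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "ankle-to-ankle distance (px)") +
    ggplot2::theme_minimal()
  if (length(seg$minima_indices)) {
    pts <- sig[sig$frame %in% seg$minima_indices, ]
    p <- p + ggplot2::geom_point(data = pts, colour = "red")
  }
  if (seg$status == "ok") {
    p <- p + ggplot2::annotate("rect", xmin = seg$start_frame,
                               xmax = seg$end_frame, ymin = -Inf, ymax = Inf,
                               alpha = 0.1, fill = "blue")
  }
  p
}
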