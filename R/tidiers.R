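# broom-style tidiers for sweep objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a top-k sweep
#'
#' One row per model x k x repetition x fold with the metric columns; the
#' selected-feature lists are dropped (see [selection_frequency()] for
#' those).
#'
#' @param x a `gait_topk_sweep`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.gait_topk_sweep <- function(x, ...) {
  dplyr::select(x$results, -"selected_features")
}

#' Glance at a top-k sweep
#'
#' @param x a `gait_topk_sweep`.
#' @param ... unused.
#' @return One-row tibble: outcome, evaluation counts, and the best mean
#'   AUC-ROC over (model, k) with its location.
#' @export
glance.gait_topk_sweep <- function(x, ...) {
  curves <- aggregate_curves(x)
  auc <- dplyr::filter(curves, .data$metric == "auc_roc")
  best <- auc[which.max(auc$mean), ]
  tibble::tibble(outcome = x$outcome, positive = x$positive,
                 n_models = length(x$models), k_min = min(x$k_range),
                 k_max = max(x$k_range), n_evaluations = nrow(x$results),
                 n_discarded_folds = nrow(x$discarded),
                 best_auc_mean = best$mean, best_auc_sd = best$sd,
                 best_auc_model = best$model, best_auc_k = best$k)
}
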