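# Exploratory sensitivity analyses around the main sweep: stratified
# metrics, per-site reruns, best/worst-predicted individuals, and
# feature-selection diagnostics. Stratified metrics pool the out-of-fold
# predictions (rather than re-scoring per fold) so small strata are not
# shredded across folds.

metrics_pooled <- function(truth, probabilities, positive, threshold = 0.5) {
  if (length(truth) == 0L) {
    return(tibble::tibble(auc_roc = NA_real_, accuracy = NA_real_,
                          mcc = NA_real_, sensitivity_pos = NA_real_,
                          sensitivity_neg = NA_real_, f1_pos = NA_real_,
                          f1_neg = NA_real_, n = 0L, auc_defined = FALSE))
  }
  y <- as.integer(as.character(truth) == positive)
  single <- length(unique(y)) < 2L
  if (!single) {
    out <- compute_metrics(truth, probabilities, positive, threshold)
    out$auc_defined <- TRUE
    return(out)
  }
  p <- as.numeric(probabilities)
  pred <- as.integer(p >= threshold)
  acc <- mean(pred == y)
  sens_pos <- if (any(y == 1L)) mean(pred[y == 1L] == 1L) else NA_real_
  sens_neg <- if (any(y == 0L)) mean(pred[y == 0L] == 0L) else NA_real_
  tibble::tibble(auc_roc = NA_real_, accuracy = acc, mcc = 0,
                 sensitivity_pos = sens_pos, sensitivity_neg = sens_neg,
                 f1_pos = NA_real_, f1_neg = NA_real_, n = length(y),
                 auc_defined = FALSE)
}

#' BMI stratum membership table
#'
#' The default body-shape strata: BMI >= 25 vs < 25 kg/m^2.
#'
#' @param meta metadata tibble with `recording_id` and `bmi`.
#' @param cutoff BMI cut point (default 25).
#' @return Tibble with `recording_id` and logical columns `bmi_ge25`,
#'   `bmi_lt25`.
#' @export
bmi_strata <- function(meta, cutoff = 25) {
  tibble::tibble(recording_id = meta$recording_id,
                 bmi_ge25 = meta$bmi >= cutoff,
                 bmi_lt25 = meta$bmi < cutoff)
}

#' Performance metrics within covariate strata
#'
#' Restricts the pooled out-of-fold predictions of a sweep to each stratum's
#' members and recomputes the metric suite. Strata with a single truth
#' class report threshold metrics only (`auc_defined = FALSE`); empty strata
#' yield an all-`NA` row, not an error.
#'
#' @param sweep a `gait_topk_sweep`.
#' @param strata tibble with `recording_id` and one logical column per
#'   stratum (see [bmi_strata()]).
#' @param k feature subset size to evaluate (default: the sweep's largest).
#' @param models models to include (default: all in the sweep).
#' @return Tibble with one row per (stratum, model) and metric columns.
#' @export
stratum_metrics <- function(sweep, strata, k = max(sweep$k_range),
                            models = sweep$models) {
  stopifnot(inherits(sweep, "gait_topk_sweep"))
  stratum_cols <- setdiff(names(strata), "recording_id")
  preds <- dplyr::filter(sweep$predictions, .data$k == !!k,
                         .data$model %in% models)
  if (!all(unique(preds$recording_id) %in% strata$recording_id)) {
    abort_gait("strata must cover every predicted sample", "gait_validation_error")
  }
  purrr::map_dfr(stratum_cols, function(sc) {
    members <- strata$recording_id[strata[[sc]]]
    purrr::map_dfr(models, function(m) {
      sub <- dplyr::filter(preds, .data$model == m,
                           .data$recording_id %in% members)
      dplyr::bind_cols(tibble::tibble(stratum = sc, model = m, k = k),
                       metrics_pooled(sub$truth, sub$probability,
                                      sweep$positive))
    })
  })
}

#' Re-run the full sweep on a site subgroup
#'
#' A complete re-execution of scaling, ranking, selection and fitting on the
#' subset only — not a filtering of pooled results. With `site = NULL` and a
#' keep-everything filter this reduces exactly to the pooled run.
#'
#' @param features labelled feature table (see [extract_cohort_features()]).
#' @param outcome outcome column name.
#' @param site site value to keep (`"thailand"` or `"india"`), or `NULL`.
#' @param keep optional logical vector selecting rows (overrides `site`).
#' @param ... passed to [run_topk_sweep()].
#' @return A `gait_topk_sweep` for the subgroup.
#' @export
subgroup_rerun <- function(features, outcome, site = NULL, keep = NULL, ...) {
  if (is.null(keep)) {
    keep <- if (is.null(site)) rep(TRUE, nrow(features)) else features$site == site
  }
  run_topk_sweep(features[keep, , drop = FALSE], outcome, ...)
}

#' Best- and worst-predicted individuals
#'
#' Scores each individual by the mean out-of-fold probability assigned to
#' their true class across repetitions (and folds), then returns the top and
#' bottom `n_top`, ties broken by recording id. Threshold-free, computed per
#' model unless models are pooled explicitly.
#'
#' @param sweep a `gait_topk_sweep`.
#' @param n_top list length (default 10); truncated with a warning if it
#'   exceeds the cohort.
#' @param model model to score (default: first in the sweep).
#' @param k feature subset size (default: the sweep's largest); `NULL` pools
#'   across all k.
#' @return A list with tibbles `best` and `worst`
#'   (`recording_id`, `mean_correct_class_probability`, `n_predictions`).
#' @export
rank_individuals <- function(sweep, n_top = 10L, model = sweep$models[1],
                             k = max(sweep$k_range)) {
  stopifnot(inherits(sweep, "gait_topk_sweep"))
  preds <- dplyr::filter(sweep$predictions, .data$model == !!model)
  if (!is.null(k)) preds <- dplyr::filter(preds, .data$k == !!k)
  scores <- preds |>
    dplyr::mutate(p_true = ifelse(.data$truth == sweep$positive,
                                  .data$probability, 1 - .data$probability)) |>
    dplyr::group_by(.data$recording_id) |>
    dplyr::summarise(mean_correct_class_probability = mean(.data$p_true),
                     n_predictions = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_correct_class_probability),
                   .data$recording_id)
  if (n_top > nrow(scores)) {
    rlang::warn(sprintf("n_top (%d) exceeds cohort size (%d); truncating",
                        n_top, nrow(scores)))
    n_top <- nrow(scores)
  }
  list(best = utils::head(scores, n_top),
       worst = utils::tail(scores, n_top) |>
         dplyr::arrange(.data$mean_correct_class_probability, .data$recording_id))
}

#' Feature-selection frequency at a given k
#'
#' For each feature, the fraction of (repetition, fold) evaluations whose
#' top-k selection contained it. Selection is model-independent (the ranking
#' model is shared), so one model's rows are counted. Frequencies sum to k
#' exactly when no folds were discarded.
#'
#' @param sweep a `gait_topk_sweep`.
#' @param k feature subset size.
#' @return Tibble `feature`, `n_selected`, `frequency`, all features
#'   included (zeros kept), sorted by frequency then name.
#' @export
selection_frequency <- function(sweep, k) {
  stopifnot(inherits(sweep, "gait_topk_sweep"))
  rows <- dplyr::filter(sweep$results, .data$k == !!k,
                        .data$model == sweep$models[1])
  if (nrow(rows) == 0L) {
    abort_gait(sprintf("no sweep results at k = %d", k), "gait_validation_error")
  }
  counts <- table(factor(unlist(rows$selected_features),
                         levels = sweep$feature_cols))
  tibble::tibble(feature = names(counts),
                 n_selected = as.integer(counts),
                 frequency = as.numeric(counts) / nrow(rows)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$feature)
}

#' Per-class feature distributions
#'
#' Descriptive summaries (mean, SD, quartiles) of named features by outcome
#' class, with a standardized mean difference (difference of class means
#' over the pooled within-class SD) as the numeric counterpart of
#' distribution plots. A zero pooled SD with separated means yields an
#' infinite SMD, flagged rather than hidden.
#'
#' @param features labelled feature table.
#' @param outcome outcome column name.
#' @param feature_names features to summarise.
#' @return Tibble with one row per (feature, class) plus the per-feature
#'   `smd` column (repeated within feature).
#' @export
feature_distributions <- function(features, outcome, feature_names) {
  missing_f <- setdiff(feature_names, names(features))
  if (length(missing_f)) {
    abort_gait(sprintf("unknown feature name(s): %s",
                       paste(missing_f, collapse = ", ")), "gait_validation_error")
  }
  y <- as.character(features[[outcome]])
  classes <- sort(unique(y))
  if (length(classes) != 2L) abort_gait("binary outcome required", "gait_validation_error")
  purrr::map_dfr(feature_names, function(fn) {
    v <- features[[fn]]
    per_class <- purrr::map_dfr(classes, function(cl) {
      vv <- v[y == cl]
      tibble::tibble(feature = fn, class = cl, n = length(vv),
                     mean = mean(vv), sd = stats::sd(vv),
                     q25 = unname(stats::quantile(vv, 0.25)),
                     median = stats::median(vv),
                     q75 = unname(stats::quantile(vv, 0.75)))
    })
    n1 <- per_class$n[1]; n2 <- per_class$n[2]
    pooled <- sqrt(((n1 - 1) * per_class$sd[1]^2 + (n2 - 1) * per_class$sd[2]^2) /
                     max(1, n1 + n2 - 2))
    delta <- per_class$mean[2] - per_class$mean[1]
    per_class$smd <- if (pooled == 0) ifelse(delta == 0, 0, Inf * sign(delta)) else delta / pooled
    per_class
  })
}
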