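# End-to-end orchestration: simulate -> segment -> extract -> evaluate ->
# sensitivity, with a manifest for reproducibility. All CSV output goes
# through a fixed-format writer so reruns with the same configuration are
# byte-identical.

#' Pipeline run configuration
#'
#' Validated bundle of every stage's settings. Unknown arguments are
#' rejected (the formals are the schema).
#'
#' @param n synthetic cohort size.
#' @param effects an [effect_config()].
#' @param noise a [noise_config()].
#' @param sex_female_frac,age_over65_frac cohort label fractions.
#' @param n_strides strides per recording.
#' @param pairs,triplets feature definitions.
#' @param n_folds,n_repetitions cross-validation plan.
#' @param ranking a [ranking_spec()].
#' @param models classifier backends to evaluate.
#' @param k_range feature subset sizes.
#' @param outcomes outcome columns to classify.
#' @param report_k feature subset size used for stratum metrics, individual
#'   rankings and the selected-features table.
#' @param n_top individuals in the best/worst lists.
#' @param nrounds boosting rounds for `hist_gb`.
#' @param base_seed integer seed for the whole run.
#' @param out_dir output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 150, effects = effect_config(),
                            noise = noise_config(failure_rate = 0.065),
                            sex_female_frac = 0.648, age_over65_frac = 0.379,
                            n_strides = 5,
                            pairs = default_distance_pairs(),
                            triplets = default_angle_triplets(),
                            n_folds = 5L, n_repetitions = 20L,
                            ranking = ranking_spec(),
                            models = c("enet_lr", "hist_gb"),
                            k_range = 1:50,
                            outcomes = c("sex", "age_group"),
                            report_k = 15L, n_top = 10L, nrounds = 100L,
                            base_seed = 1L, out_dir = tempfile("gaitpipe_run_")) {
  pairs <- validate_pair_set(pairs)
  triplets <- validate_triplet_set(triplets)
  n_features <- 4L * (nrow(pairs) + nrow(triplets)) + 1L
  if (max(k_range) > n_features) {
    abort_gait(sprintf("k_max (%d) exceeds the feature count (%d)",
                       max(k_range), n_features), "gait_validation_error")
  }
  if (!report_k %in% k_range) {
    abort_gait("report_k must be inside k_range", "gait_validation_error")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates a cohort, segments gait cycles, extracts the 109-feature table,
#' runs the leakage-guarded top-k sweep for every outcome and model, runs
#' the sensitivity analyses, and writes every result as a fixed-format CSV
#' plus a JSON manifest (configuration snapshot, seed, per-stage row counts,
#' feasibility proportion, and a content hash per output file). Rerunning
#' with an identical configuration reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return The run directory path, invisibly; the manifest as the `manifest`
#'   attribute.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_csv_stable(df, path)
    outputs <<- c(outputs, name)
  }

  say("simulating cohort (n = %d)", config$n)
  cohort <- sample_cohort(config$n, config$sex_female_frac,
                          config$age_over65_frac, config$effects,
                          config$noise, n_strides = config$n_strides,
                          rng_seed = config$base_seed)
  meta <- dplyr::select(cohort, -"pose")
  emit(meta, "meta.csv")

  say("segmenting gait cycles")
  segments <- segment_cohort(cohort)
  feas <- feasibility(segments)
  emit(dplyr::select(segments, -"segment"), "segments.csv")
  say("extraction feasible for %d / %d recordings (%.1f%%)",
      feas$n_success, feas$n_total, 100 * feas$proportion)

  say("extracting features")
  features <- extract_cohort_features(cohort, segments,
                                      pairs = config$pairs,
                                      triplets = config$triplets)
  emit(features, "features.csv")

  plan <- cv_plan(config$n_folds, config$n_repetitions, config$base_seed)
  sweeps <- list()
  for (outcome in config$outcomes) {
    say("evaluating outcome '%s' (k = %d..%d, %d x %d folds)", outcome,
        min(config$k_range), max(config$k_range),
        plan$n_repetitions, plan$n_folds)
    sw <- run_topk_sweep(features, outcome, k_range = config$k_range,
                         plan = plan, models = config$models,
                         ranking = config$ranking, nrounds = config$nrounds)
    sweeps[[outcome]] <- sw
    emit(tidy(sw), sprintf("eval_results_%s.csv", outcome))
    emit(aggregate_curves(sw), sprintf("curves_%s.csv", outcome))
    emit(sw$predictions, sprintf("predictions_%s.csv", outcome))
    sel <- sw$results |>
      dplyr::filter(.data$k == config$report_k,
                    .data$model == sw$models[1]) |>
      dplyr::select("repetition", "fold", "selected_features") |>
      tidyr::unnest_longer("selected_features", values_to = "feature") |>
      dplyr::group_by(.data$repetition, .data$fold) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
    emit(sel, sprintf("selected_features_%s.csv", outcome))

    say("sensitivity analyses for '%s'", outcome)
    emit(stratum_metrics(sw, bmi_strata(meta), k = config$report_k),
         sprintf("stratum_metrics_%s.csv", outcome))
    for (m in sw$models) {
      ind <- rank_individuals(sw, n_top = config$n_top, model = m,
                              k = config$report_k)
      emit(dplyr::bind_rows(dplyr::mutate(ind$best, list = "best"),
                            dplyr::mutate(ind$worst, list = "worst")),
           sprintf("individuals_%s_%s.csv", outcome, m))
    }
    emit(selection_frequency(sw, k = config$report_k),
         sprintf("selection_frequency_%s.csv", outcome))
    top_feats <- utils::head(selection_frequency(sw, config$report_k)$feature, 5L)
    emit(feature_distributions(features, outcome, top_feats),
         sprintf("feature_distributions_%s.csv", outcome))
  }

  cfg_snapshot <- config
  cfg_snapshot$pairs <- as.data.frame(config$pairs)
  cfg_snapshot$triplets <- as.data.frame(config$triplets)
  cfg_snapshot$effects <- unclass(config$effects)
  cfg_snapshot$noise <- unclass(config$noise)
  cfg_snapshot$ranking <- unclass(config$ranking)
  cfg_snapshot$out_dir <- NULL
  manifest <- list(
    seed = config$base_seed,
    config = unclass(cfg_snapshot),
    feasibility = as.list(feas),
    n_feature_columns = length(feature_names(config$pairs, config$triplets)),
    row_counts = list(cohort = nrow(cohort), segments = nrow(segments),
                      features = nrow(features)),
    files = lapply(stats::setNames(outputs, outputs), function(f)
      list(md5 = unname(tools::md5sum(file.path(config$out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("run complete: %s", config$out_dir)
  out <- config$out_dir
  attr(out, "manifest") <- manifest
  attr(out, "sweeps") <- sweeps
  invisible(out)
}

#' Render plots and summary tables from a completed run
#'
#' Reads the run's CSV artifacts and writes performance-vs-k plots (one PDF
#' per outcome and metric) plus a plain-text summary. Plot *data* always
#' exists as CSV already; the plots are conveniences. Regeneration is
#' idempotent.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @param metrics metrics to plot.
#' @return Invisible character vector of files written.
#' @export
render_report <- function(run_dir, metrics = c("auc_roc", "accuracy", "mcc")) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort_gait(sprintf("incomplete run: missing %s", manifest_path), "gait_io_error")
  }
  manifest <- jsonlite::read_json(manifest_path)
  curve_files <- list.files(run_dir, "^curves_.*\\.csv$")
  if (!length(curve_files)) {
    abort_gait("incomplete run: no curves_*.csv artifacts", "gait_io_error")
  }
  written <- character()
  for (cf in curve_files) {
    outcome <- sub("^curves_(.*)\\.csv$", "\\1", cf)
    curves <- utils::read.csv(file.path(run_dir, cf))
    for (metric in intersect(metrics, unique(curves$metric))) {
      sub_c <- curves[curves$metric == metric, ]
      p <- ggplot2::ggplot(sub_c, ggplot2::aes(x = .data$k, y = .data$mean,
                                               colour = .data$model,
                                               fill = .data$model)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             alpha = 0.15, colour = NA) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "number of selected features (k)", y = metric,
                      title = sprintf("%s, outcome %s", metric, outcome)) +
        ggplot2::theme_minimal()
      f <- file.path(run_dir, sprintf("curve_%s_%s.pdf", outcome, metric))
      ggplot2::ggsave(f, p, width = 7, height = 4.5)
      written <- c(written, f)
    }
  }
  summary_path <- file.path(run_dir, "report.txt")
  feas <- manifest$feasibility
  lines <- c(sprintf("gaitpipe run (seed %s)", manifest$seed),
             sprintf("feasibility: %d / %d recordings (%.1f%%)",
                     feas$n_success, feas$n_total, 100 * feas$proportion),
             sprintf("feature columns: %s", manifest$n_feature_columns),
             sprintf("outcomes: %s",
                     paste(sub("^curves_(.*)\\.csv$", "\\1", curve_files),
                           collapse = ", ")))
  writeLines(lines, summary_path)
  invisible(c(written, summary_path))
}
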