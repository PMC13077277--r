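# Leakage-guarded repeated stratified cross-validation with a top-k feature
# sweep. Everything fitted -- the z-scaler, the elastic-net feature ranking,
# and the classifiers -- sees only the training fold of the current split;
# the held-out fold is touched exactly once, for prediction. Folds are drawn
# once per repetition and reused across every k and both models, so the
# performance-vs-k curves differ only by feature count, not by resampling
# noise.

#' Cross-validation plan
#'
#' @param n_folds folds per repetition (default 5).
#' @param n_repetitions independent stratified splits (default 20, giving
#'   100 train-test evaluations per feature subset size).
#' @param base_seed integer seed from which all fold and model seeds are
#'   derived deterministically.
#' @return A list of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 5L, n_repetitions = 20L, base_seed = 1L) {
  if (n_folds < 2L) abort_gait("n_folds must be >= 2", "gait_validation_error")
  if (n_repetitions < 1L) abort_gait("n_repetitions must be >= 1", "gait_validation_error")
  structure(list(n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 base_seed = as.integer(base_seed)),
            class = "cv_plan")
}

#' Elastic-net ranking specification
#'
#' Hyperparameters of the elastic-net-penalised logistic regression used both
#' to rank features by absolute coefficient magnitude and as the linear
#' classifier. `regularization_strength` is expressed in scaled units: the
#' penalty applied per observation is `regularization_strength / n_train`,
#' so its meaning does not drift with fold size.
#'
#' @param l1_ratio mixing between L1 (`1`) and L2 (`0`) penalties.
#' @param regularization_strength total penalty weight (> 0).
#' @return A list of class `ranking_spec`.
#' @export
ranking_spec <- function(l1_ratio = 0.5, regularization_strength = 1) {
  if (l1_ratio < 0 || l1_ratio > 1) abort_gait("l1_ratio must lie in [0, 1]", "gait_validation_error")
  assert_scalar_num(regularization_strength, "regularization_strength", positive = TRUE)
  structure(list(l1_ratio = l1_ratio,
                 regularization_strength = regularization_strength,
                 class_weighting = "balanced"),
            class = "ranking_spec")
}

#' Stratified fold assignment
#'
#' Distributes each outcome class across folds as evenly as possible (fold
#' class counts never differ by more than one from the proportional share);
#' deterministic given the seed.
#'
#' @param labels outcome vector (two or more classes).
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1:n_folds`, one per sample.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) {
    abort_gait("labels must contain at least two classes", "gait_validation_error")
  }
  small <- names(tab)[tab < n_folds]
  if (length(small)) {
    abort_gait(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                       small[1], tab[[small[1]]], n_folds),
               "gait_validation_error")
  }
  n_folds <- as.integer(n_folds)
  out <- integer(length(labels))
  totals <- integer(n_folds)
  with_seed(seed, {
    for (cls in names(tab)) {
      idx <- sample(which(labels == cls))
      n_c <- length(idx)
      counts <- rep(n_c %/% n_folds, n_folds)
      rem <- n_c %% n_folds
      if (rem > 0L) {
        # leftovers go to the currently lightest folds (random tie-break),
        # keeping total fold sizes as even as the class sizes allow
        lightest <- order(totals, sample.int(n_folds))[seq_len(rem)]
        counts[lightest] <- counts[lightest] + 1L
      }
      out[idx] <- rep.int(seq_len(n_folds), counts)
      totals <- totals + counts
    }
  })
  out
}

#' Z-score scaling fitted on training data only
#'
#' `zscale()` fits per-feature mean and population SD on the training matrix
#' and returns both the scaler and the scaled matrix; `apply_zscale()`
#' applies a fitted scaler to any matrix with the same columns. Features
#' constant in training scale to 0 everywhere (train and test), so they
#' carry no information rather than exploding.
#'
#' @param train numeric matrix (samples x features), nonempty.
#' @return `zscale()`: list with `scaler` (means, sds, feature names) and
#'   `scaled`; `apply_zscale()`: the scaled matrix.
#' @export
zscale <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) abort_gait("empty training matrix", "gait_validation_error")
  mu <- colMeans(train)
  sds <- sqrt(colMeans(sweep(train, 2, mu)^2))
  scaler <- list(mean = mu, sd = sds, features = colnames(train))
  list(scaler = scaler, scaled = apply_zscale(scaler, train))
}

#' @rdname zscale
#' @param scaler a fitted scaler from `zscale()`.
#' @param mat matrix to transform with the training statistics.
#' @export
apply_zscale <- function(scaler, mat) {
  mat <- as.matrix(mat)
  if (!is.null(scaler$features) && !is.null(colnames(mat)) &&
      !identical(colnames(mat), scaler$features)) {
    abort_gait("matrix columns do not match the fitted scaler", "gait_validation_error")
  }
  sds <- ifelse(scaler$sd == 0, 1, scaler$sd)
  out <- sweep(sweep(mat, 2, scaler$mean), 2, sds, "/")
  out[, scaler$sd == 0] <- 0
  out
}

#' Balanced per-sample class weights
#'
#' Weight for a member of class c is `n_total / (n_classes * n_c)`, so each
#' class contributes equally to the loss and the weights sum to `n_total`.
#'
#' @param labels outcome vector with >= 2 classes present.
#' @return Numeric weight per sample.
#' @export
balanced_weights <- function(labels) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) abort_gait("balanced weights need >= 2 classes", "gait_validation_error")
  w <- length(labels) / (length(tab) * tab)
  as.numeric(w[labels])
}

# elastic-net logistic fit at a single fixed lambda; returns the coefficient
# vector (no intercept). Retries with a larger iteration budget on
# convergence warnings.
enet_coefs <- function(x, y01, weights, spec) {
  lambda <- spec$regularization_strength / nrow(x)
  fit_once <- function(maxit) {
    glmnet::glmnet(x, y01, family = "binomial", weights = weights,
                   alpha = spec$l1_ratio, lambda = lambda,
                   standardize = FALSE, maxit = maxit)
  }
  fit <- withCallingHandlers(
    fit_once(1e5),
    warning = function(w) invokeRestart("muffleWarning"))
  if (fit$jerr != 0) fit <- fit_once(1e6)
  as.numeric(fit$beta[, 1])
}

#' Rank features by elastic-net coefficient magnitude
#'
#' Fits an elastic-net-penalised logistic regression with balanced class
#' weights to the scaled training matrix and orders features by the absolute
#' magnitude of their coefficients, descending. Ties (including exact zeros)
#' are broken by feature-name lexicographic order so top-k selection is
#' reproducible.
#'
#' @param scaled_train scaled training matrix with column names.
#' @param labels binary outcome for the training rows.
#' @param spec a [ranking_spec()].
#' @param positive the class encoded as 1.
#' @return Character vector: all feature names, best first.
#' @export
rank_features <- function(scaled_train, labels, spec = ranking_spec(),
                          positive = NULL) {
  scaled_train <- as.matrix(scaled_train)
  if (is.null(colnames(scaled_train))) {
    abort_gait("scaled_train must have column names", "gait_validation_error")
  }
  y01 <- encode_binary(labels, positive)
  w <- balanced_weights(labels)
  beta <- abs(enet_coefs(scaled_train, y01, w, spec))
  nm <- colnames(scaled_train)
  nm[order(-beta, nm, method = "radix")]
}

encode_binary <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    abort_gait("binary outcome required", "gait_validation_error")
  }
  if (is.null(positive)) positive <- classes[2L]
  if (!positive %in% classes) {
    abort_gait(sprintf("positive class '%s' absent from labels", positive),
               "gait_validation_error")
  }
  as.integer(labels == positive)
}

hist_gb_params <- function() {
  # mirrors the reference histogram-GB defaults: <=255 bins, learning rate
  # 0.1, 31 leaves, ~20-sample leaves (hessian-equivalent min_child_weight
  # at p ~ 0.5), no L2, no early stopping
  list(objective = "binary:logistic", tree_method = "hist", max_bin = 255,
       eta = 0.1, grow_policy = "lossguide", max_leaves = 31, max_depth = 0,
       lambda = 0, min_child_weight = 5, nthread = 1)
}

#' Fit a classifier and predict held-out probabilities
#'
#' Two backends: `enet_lr`, the elastic-net logistic regression (also the
#' ranking model), and `hist_gb`, gradient-boosted trees over binned feature
#' histograms (<= 255 bins, learning rate 0.1, no early stopping). Both are
#' trained with the supplied per-sample weights; predictions are class-1
#' probabilities for the test rows. Deterministic given inputs and seed.
#'
#' @param model `"enet_lr"` or `"hist_gb"`.
#' @param train,test numeric matrices sharing feature columns.
#' @param labels01 0/1 outcome for the training rows.
#' @param weights per-sample training weights.
#' @param spec a [ranking_spec()] (used by `enet_lr`).
#' @param nrounds boosting rounds for `hist_gb` (default 100).
#' @param seed integer seed (consumed by `hist_gb`).
#' @return Numeric vector of probabilities in \[0, 1\], one per test row.
#' @export
fit_predict <- function(model = c("enet_lr", "hist_gb"), train, labels01,
                        weights, test, spec = ranking_spec(), nrounds = 100L,
                        seed = 1L) {
  model <- match.arg(model)
  train <- as.matrix(train); test <- as.matrix(test)
  if (!identical(colnames(train), colnames(test))) {
    abort_gait("train and test must share feature columns", "gait_validation_error")
  }
  if (model == "enet_lr") {
    # glmnet needs >= 2 columns; pad with an all-zero dummy for k = 1
    pad <- ncol(train) == 1L
    tr <- if (pad) cbind(train, .dummy = 0) else train
    te <- if (pad) cbind(test, .dummy = 0) else test
    lambda <- spec$regularization_strength / nrow(tr)
    fit <- withCallingHandlers(
      glmnet::glmnet(tr, labels01, family = "binomial", weights = weights,
                     alpha = spec$l1_ratio, lambda = lambda,
                     standardize = FALSE, maxit = 1e5),
      warning = function(w) invokeRestart("muffleWarning"))
    p <- as.numeric(stats::predict(fit, te, type = "response"))
  } else {
    dtrain <- xgboost::xgb.DMatrix(train, label = labels01, weight = weights,
                                   nthread = 1)
    params <- c(hist_gb_params(), list(seed = as.integer(seed)))
    bst <- with_seed(seed,
                     xgboost::xgb.train(params = params, data = dtrain,
                                        nrounds = nrounds, verbose = 0))
    p <- as.numeric(stats::predict(bst, xgboost::xgb.DMatrix(test, nthread = 1)))
  }
  pmin(pmax(p, 0), 1)
}

#' Classification metric suite
#'
#' AUC-ROC by the rank (Mann-Whitney) formulation with half credit for score
#' ties; accuracy, per-class sensitivity, per-class F1 and the Matthews
#' correlation coefficient from hard labels at the given threshold. MCC is
#' defined as 0 when any confusion-matrix margin is 0; an F1 with an empty
#' denominator is 0.
#'
#' @param truth binary outcome vector.
#' @param probabilities class-positive probabilities.
#' @param positive the class treated as positive (default: the
#'   lexicographically later class).
#' @param threshold hard-label cut-off (default 0.5).
#' @return A one-row tibble: `auc_roc`, `accuracy`, `mcc`,
#'   `sensitivity_pos`, `sensitivity_neg`, `f1_pos`, `f1_neg`, `n`.
#' @export
compute_metrics <- function(truth, probabilities, positive = NULL,
                            threshold = 0.5) {
  if (length(unique(as.character(truth))) < 2L) {
    abort_gait("AUC undefined: single-class truth", "gait_metric_error")
  }
  y <- encode_binary(truth, positive)
  p <- as.numeric(probabilities)
  r <- rank(p, ties.method = "average")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  acc <- (tp + tn) / length(y)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  sens_pos <- tp / n1
  sens_neg <- tn / n0
  f1 <- function(tp_, fp_, fn_) if (2 * tp_ + fp_ + fn_ == 0) 0 else 2 * tp_ / (2 * tp_ + fp_ + fn_)
  tibble::tibble(auc_roc = auc, accuracy = acc, mcc = mcc,
                 sensitivity_pos = sens_pos, sensitivity_neg = sens_neg,
                 f1_pos = f1(tp, fp, fn), f1_neg = f1(tn, fn, fp),
                 n = length(y))
}

default_positive <- function(outcome) {
  switch(outcome, sex = "female", age_group = "over65eq", NULL)
}

#' Run the leakage-guarded top-k sweep
#'
#' For every repetition, a stratified fold split is drawn; for every fold,
#' the z-scaler and the elastic-net feature ranking are fitted on the
#' training rows only; then for every feature subset size k and every model
#' the top-k features are selected, the model fitted, and the held-out fold
#' predicted. With the default plan each (model, k) accumulates 5 x 20 = 100
#' train-test evaluations. Single-class test folds (possible at small n)
#' are discarded and counted, not imputed. All seeds derive from the plan's
#' `base_seed`; reruns are bit-identical.
#'
#' @param features tibble with `recording_id`, feature columns and the
#'   outcome column.
#' @param outcome name of the outcome column (e.g. `"sex"`, `"age_group"`).
#' @param k_range feature subset sizes (default 1:50).
#' @param plan a [cv_plan()].
#' @param models character subset of `c("enet_lr", "hist_gb")`.
#' @param ranking a [ranking_spec()].
#' @param feature_cols feature column names; by default every numeric column
#'   except identifiers, outcomes and covariates.
#' @param positive positive class (default per outcome: `female`,
#'   `over65eq`).
#' @param nrounds boosting rounds for `hist_gb`.
#' @return An object of class `gait_topk_sweep`: list with `results` (one
#'   row per model x k x repetition x fold, metric columns and a
#'   `selected_features` list-column), `predictions` (out-of-fold
#'   probabilities per sample), `discarded`, and the run settings.
#' @export
run_topk_sweep <- function(features, outcome, k_range = 1:50,
                           plan = cv_plan(), models = c("enet_lr", "hist_gb"),
                           ranking = ranking_spec(), feature_cols = NULL,
                           positive = default_positive(outcome),
                           nrounds = 100L) {
  stopifnot(inherits(plan, "cv_plan"))
  models <- match.arg(models, c("enet_lr", "hist_gb"), several.ok = TRUE)
  if (!outcome %in% names(features)) {
    abort_gait(sprintf("outcome column '%s' not found", outcome), "gait_validation_error")
  }
  if (is.null(feature_cols)) {
    drop <- c("recording_id", "sex", "age_group", "site", "age_years", "bmi", outcome)
    feature_cols <- names(features)[vapply(features, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, drop)
  }
  if (max(k_range) > length(feature_cols)) {
    abort_gait(sprintf("k_max (%d) exceeds the number of features (%d)",
                       max(k_range), length(feature_cols)),
               "gait_validation_error")
  }
  x_all <- as.matrix(features[, feature_cols])
  storage.mode(x_all) <- "double"
  y <- as.character(features[[outcome]])
  ids <- if ("recording_id" %in% names(features)) features$recording_id else
    sprintf("row%04d", seq_len(nrow(features)))
  if (nrow(x_all) < 2L * plan$n_folds) {
    abort_gait("need at least 2 samples per fold", "gait_validation_error")
  }
  if (is.null(positive)) positive <- sort(unique(y))[2L]
  y01_all <- encode_binary(y, positive)

  res_rows <- list(); pred_rows <- list(); disc_rows <- list()
  for (rep_i in seq_len(plan$n_repetitions)) {
    folds <- stratified_folds(y, plan$n_folds,
                              seed = derive_seed(plan$base_seed, 101, rep_i))
    for (fold_i in seq_len(plan$n_folds)) {
      te <- folds == fold_i; tr <- !te
      if (length(unique(y[te])) < 2L) {
        disc_rows[[length(disc_rows) + 1L]] <-
          tibble::tibble(repetition = rep_i, fold = fold_i,
                         recording_ids = list(ids[te]))
        next
      }
      zs <- zscale(x_all[tr, , drop = FALSE])
      xtr <- zs$scaled
      xte <- apply_zscale(zs$scaler, x_all[te, , drop = FALSE])
      w <- balanced_weights(y[tr])
      ranking_order <- rank_features(xtr, y[tr], ranking, positive = positive)
      for (k in k_range) {
        sel <- ranking_order[seq_len(k)]
        xtr_k <- xtr[, sel, drop = FALSE]
        xte_k <- xte[, sel, drop = FALSE]
        for (model in models) {
          p <- fit_predict(model, xtr_k, y01_all[tr], w, xte_k,
                           spec = ranking, nrounds = nrounds,
                           seed = derive_seed(plan$base_seed, 202, rep_i, fold_i))
          met <- compute_metrics(y[te], p, positive = positive)
          res_rows[[length(res_rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(model = model, k = k, repetition = rep_i,
                           fold = fold_i),
            met,
            tibble::tibble(selected_features = list(sel)))
          pred_rows[[length(pred_rows) + 1L]] <-
            tibble::tibble(model = model, k = k, repetition = rep_i,
                           fold = fold_i, recording_id = ids[te],
                           truth = y[te], probability = p)
        }
      }
    }
  }
  structure(list(results = dplyr::bind_rows(res_rows),
                 predictions = dplyr::bind_rows(pred_rows),
                 discarded = dplyr::bind_rows(disc_rows),
                 outcome = outcome, positive = positive, plan = plan,
                 models = models, k_range = k_range,
                 feature_cols = feature_cols),
            class = "gait_topk_sweep")
}

#' @exportS3Method base::print
print.gait_topk_sweep <- function(x, ...) {
  cat(sprintf("<gait_topk_sweep> outcome=%s, models=%s, k=%d..%d, %d evaluations (%d discarded folds)\n",
              x$outcome, paste(x$models, collapse = "+"),
              min(x$k_range), max(x$k_range), nrow(x$results),
              nrow(x$discarded)))
  invisible(x)
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate sweep results into performance-vs-k curves
#'
#' Arithmetic mean and population SD of every metric over the (up to) 100
#' evaluations, per model and feature subset size. Discarded folds are
#' excluded; their count is reported in the `n_discarded` attribute.
#'
#' @param sweep a `gait_topk_sweep`, or its `results` tibble.
#' @return A tibble with one row per (model, k, metric): `mean`, `sd`, `n`.
#' @export
aggregate_curves <- function(sweep) {
  results <- if (inherits(sweep, "gait_topk_sweep")) sweep$results else sweep
  metric_cols <- intersect(c("auc_roc", "accuracy", "mcc", "sensitivity_pos",
                             "sensitivity_neg", "f1_pos", "f1_neg"),
                           names(results))
  out <- results |>
    dplyr::select(dplyr::all_of(c("model", "k", metric_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::group_by(.data$model, .data$k, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd_pop(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$model, .data$k, .data$metric)
  attr(out, "n_discarded") <- if (inherits(sweep, "gait_topk_sweep"))
    nrow(sweep$discarded) else 0L
  out
}
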