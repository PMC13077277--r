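test_that("stratified folds spread every class evenly and balance totals", {
  y <- c(rep("a", 12), rep("b", 8))
  f <- stratified_folds(y, 5, seed = 3)
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 4))
  for (cls in c("a", "b")) {
    counts <- tabulate(f[y == cls], 5)
    share <- sum(y == cls) / 5
    expect_true(all(counts >= floor(share) & counts <= ceiling(share)))
  }
  # brute-force the <= 1 deviation rule on odd shapes
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1); k <- sample(2:5, 1)
    yy <- sample(c(rep("x", n1), rep("y", n0)))
    ff <- stratified_folds(yy, k, seed = i)
    for (cls in c("x", "y")) {
      counts <- tabulate(ff[yy == cls], k)
      expect_lte(max(counts) - min(counts), 1)
    }
  }
  expect_identical(stratified_folds(y, 5, seed = 3),
                   stratified_folds(y, 5, seed = 3))
  expect_error(stratified_folds(rep("a", 10), 5), class = "gait_validation_error")
  expect_error(stratified_folds(c(rep("a", 3), rep("b", 9)), 5),
               class = "gait_validation_error")
})

test_that("z-scaling is fitted on training statistics only", {
  tr <- matrix(c(1, 3, 5, 5), 2, dimnames = list(NULL, c("f1", "f2")))
  zs <- zscale(tr)
  expect_equal(unname(zs$scaled[, "f1"]), c(-1, 1))   # population SD
  expect_true(all(zs$scaled[, "f2"] == 0))            # constant column
  te <- matrix(c(9, 7), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  st <- apply_zscale(zs$scaler, te)
  expect_equal(unname(st[1, "f1"]), (9 - 2) / 1)
  expect_equal(unname(st[1, "f2"]), 0)
  expect_equal(apply_zscale(zs$scaler, tr), zs$scaled)
})

test_that("balanced weights follow n/(n_classes * n_c) and sum to n", {
  w <- balanced_weights(c(rep("a", 7), rep("b", 3)))
  expect_equal(unique(w[1:7]), 10 / 14)
  expect_equal(unique(w[8:10]), 10 / 6)
  expect_equal(sum(w), 10)
  expect_equal(unique(balanced_weights(rep(c("a", "b"), 5))), 1)
  expect_error(balanced_weights(rep("a", 4)), class = "gait_validation_error")
})

test_that("the elastic-net ranking recovers an injected signal feature", {
  hits <- vapply(1:100, function(s) {
    fe <- toy_features(n = 200, p_noise = 49, seed = s)
    x <- as.matrix(fe[, c("signal", sprintf("noise%02d", 1:49))])
    sc <- zscale(x)$scaled
    rank_features(sc, fe$outcome)[1] == "signal"
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("ranking ties break lexicographically and duplicates do not reorder others", {
  # identical columns -> identical |coefficients| -> name order
  x <- matrix(rnorm(40), 20, 2)
  x <- cbind(x[, 1], x[, 1], x[, 1])
  colnames(x) <- c("zeta", "alpha", "mid")
  y <- rep(c("a", "b"), 10)
  r <- rank_features(zscale(x)$scaled, y)
  expect_identical(r, sort(r))
  # duplicating a column never reorders the other features
  set.seed(9)
  for (i in 1:50) {
    n <- 150
    yy <- rep(c("a", "b"), length.out = n)
    betas <- c(1, 0.8, 0.6, 0.4, 0.2, 0)
    xx <- sapply(betas, function(b) ifelse(yy == "b", b, -b) + rnorm(n))
    colnames(xx) <- sprintf("f%d", 1:6)
    base_rank <- rank_features(zscale(xx)$scaled, yy)
    dup_col <- sample(1:6, 1)
    xd <- cbind(xx, dup = xx[, dup_col])
    dup_rank <- rank_features(zscale(xd)$scaled, yy)
    fdup <- sprintf("f%d", dup_col)
    expect_identical(dup_rank[!(dup_rank %in% c("dup", fdup))],
                     base_rank[base_rank != fdup])
  }
})

test_that("both classifiers separate a separable toy problem and are deterministic", {
  set.seed(2)
  n <- 60
  y01 <- rep(0:1, n / 2)
  x <- cbind(a = y01 * 2 - 1 + rnorm(n, 0, 0.05), b = rnorm(n))
  te_idx <- 41:60
  w <- rep(1, 40)
  for (m in c("enet_lr", "hist_gb")) {
    p <- fit_predict(m, x[1:40, ], y01[1:40], w, x[te_idx, ], seed = 5)
    expect_equal(compute_metrics(y01[te_idx], p)$auc_roc, 1)
    p2 <- fit_predict(m, x[1:40, ], y01[1:40], w, x[te_idx, ], seed = 5)
    expect_identical(p, p2)
  }
  expect_error(fit_predict("enet_lr", x[1:40, ], y01[1:40], w,
                           x[te_idx, 1, drop = FALSE]),
               class = "gait_validation_error")
})

test_that("permuted labels give chance-level test AUC", {
  set.seed(64)
  n <- 150
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, sprintf("f%d", 1:10)))
  y01 <- sample(rep(0:1, n / 2))
  tr <- 1:100; te <- 101:150
  for (m in c("enet_lr", "hist_gb")) {
    p <- fit_predict(m, x[tr, ], y01[tr], rep(1, 100), x[te, ], seed = 8)
    auc <- compute_metrics(y01[te], p)$auc_roc
    expect_gt(auc, 0.3); expect_lt(auc, 0.7)
  }
})

test_that("the metric suite matches hand-worked confusion examples", {
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2))
  expect_equal(m$auc_roc, 1); expect_equal(m$accuracy, 1); expect_equal(m$mcc, 1)
  expect_equal(compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2))$auc_roc, 0.75)
  # TP=3 FP=1 FN=2 TN=4
  truth <- c(rep(1, 5), rep(0, 5))
  probs <- c(rep(0.9, 3), rep(0.1, 2), 0.9, rep(0.1, 4))
  m2 <- compute_metrics(truth, probs)
  expect_equal(m2$mcc, 10 / sqrt(600))
  expect_equal(m2$sensitivity_pos, 0.6)
  expect_equal(m2$sensitivity_neg, 0.8)
  expect_error(compute_metrics(rep(1, 4), runif(4)), class = "gait_metric_error")
})

test_that("AUC agrees with the brute-force pairwise oracle and pROC", {
  set.seed(17)
  for (i in 1:500) {
    n <- sample(6:40, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y <- c(0, 1, y[-(1:2)])
    p <- round(runif(n), sample(1:3, 1))   # coarse grid to force ties
    expect_equal(compute_metrics(y, p)$auc_roc, oracle_auc(y, p))
  }
  skip_if_not_installed("pROC")
  set.seed(18)
  y <- sample(c(0, 1), 80, replace = TRUE)
  p <- runif(80)
  expect_equal(compute_metrics(y, p)$auc_roc,
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
})

test_that("AUC is invariant to monotone transforms; MCC to label swaps", {
  set.seed(23)
  y <- rep(c(0, 1), 20)
  p <- runif(40)
  expect_equal(compute_metrics(y, p^3)$auc_roc, compute_metrics(y, p)$auc_roc)
  m1 <- compute_metrics(y, p)
  m2 <- compute_metrics(1 - y, 1 - p)
  expect_equal(m2$mcc, m1$mcc)
  expect_equal(m2$sensitivity_pos, m1$sensitivity_neg)
})

test_that("the sweep is leakage-guarded, conserves folds, and reruns identically", {
  fe <- toy_features(n = 40, p_noise = 7, seed = 4)
  plan <- cv_plan(4, 2, base_seed = 6)
  sw <- run_topk_sweep(fe, "outcome", k_range = c(2, 4), plan = plan,
                       nrounds = 20)
  # fold conservation: every sample tested exactly once per repetition per (model, k)
  per_cell <- sw$predictions |>
    dplyr::count(.data$model, .data$k, .data$repetition, .data$recording_id)
  expect_true(all(per_cell$n == 1))
  expect_identical(nrow(sw$results), 4L * 2L * 2L * 2L)
  # rerun determinism
  sw2 <- run_topk_sweep(fe, "outcome", k_range = c(2, 4), plan = plan,
                        nrounds = 20)
  expect_identical(sw$results$auc_roc, sw2$results$auc_roc)
  expect_identical(sw$predictions$probability, sw2$predictions$probability)

  # leakage guard: corrupt one sample's features; in folds where it is held
  # out, the ranking (hence selection) and the other samples' predictions
  # must be untouched
  victim <- "r007"
  fe_mut <- fe
  mut_cols <- c("signal", sprintf("noise%02d", 1:7))
  fe_mut[fe_mut$recording_id == victim, mut_cols] <-
    fe_mut[fe_mut$recording_id == victim, mut_cols] + 1000
  sw_mut <- run_topk_sweep(fe_mut, "outcome", k_range = c(2, 4), plan = plan,
                           nrounds = 20)
  folds_of <- sw$predictions |>
    dplyr::filter(.data$recording_id == victim) |>
    dplyr::distinct(.data$repetition, .data$fold)
  for (r in seq_len(nrow(folds_of))) {
    rep_i <- folds_of$repetition[r]; fold_i <- folds_of$fold[r]
    pick <- function(s) s$results |>
      dplyr::filter(.data$repetition == rep_i, .data$fold == fold_i)
    expect_identical(pick(sw)$selected_features, pick(sw_mut)$selected_features)
    pred <- function(s) s$predictions |>
      dplyr::filter(.data$repetition == rep_i, .data$fold == fold_i,
                    .data$recording_id != victim) |>
      dplyr::arrange(.data$model, .data$k, .data$recording_id)
    expect_identical(pred(sw)$probability, pred(sw_mut)$probability)
  }
})

test_that("curve aggregation reproduces hand arithmetic", {
  res <- tibble::tibble(model = "m", k = c(1, 1, 2, 2),
                        auc_roc = c(0.5, 0.7, 0.8, 0.8))
  cv <- aggregate_curves(res)
  expect_equal(cv$mean, c(0.6, 0.8))
  expect_equal(cv$sd, c(0.1, 0))
  expect_equal(cv$n, c(2L, 2L))
})

test_that("tidy and glance expose the sweep in broom shape", {
  fe <- toy_features(n = 30, p_noise = 5, seed = 2)
  sw <- run_topk_sweep(fe, "outcome", k_range = 2, plan = cv_plan(3, 1, 5),
                       models = "enet_lr", nrounds = 10)
  td <- tidy(sw)
  expect_s3_class(td, "tbl_df")
  expect_false("selected_features" %in% names(td))
  gl <- glance(sw)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$outcome, "outcome")
  expect_true(gl$best_auc_mean >= 0 && gl$best_auc_mean <= 1)
})
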