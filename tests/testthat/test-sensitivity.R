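make_sweep <- function(fe, reps = 3, k = 5, seed = 2, models = "enet_lr") {
  run_topk_sweep(fe, "outcome", k_range = k, plan = cv_plan(5, reps, seed),
                 models = models, nrounds = 20)
}

test_that("duplicate full-cohort strata report identical metrics", {
  fe <- toy_features(n = 50, p_noise = 9, seed = 6)
  sw <- make_sweep(fe)
  strata <- tibble::tibble(recording_id = fe$recording_id,
                           all_a = TRUE, all_b = TRUE)
  sm <- stratum_metrics(sw, strata, k = 5)
  expect_identical(sm$auc_roc[1], sm$auc_roc[2])
  expect_identical(sm$mcc[1], sm$mcc[2])
})

test_that("tiny or empty strata degrade gracefully", {
  fe <- toy_features(n = 50, p_noise = 9, seed = 6)
  sw <- make_sweep(fe)
  strata <- tibble::tibble(recording_id = fe$recording_id,
                           one = fe$recording_id == fe$recording_id[1],
                           none = FALSE)
  sm <- stratum_metrics(sw, strata, k = 5)
  expect_false(sm$auc_defined[sm$stratum == "one"])
  expect_identical(sm$n[sm$stratum == "none"], 0L)
})

test_that("an injected stratum degradation shows up as lower stratum AUC", {
  flagged <- sprintf("rec%04d", (1:5) * 7)
  ok <- vapply(1:6, function(r) {
    co <- atypical_cohort(50, (1:5) * 7, r)
    fe <- extract_cohort_features(co)
    sw <- run_topk_sweep(fe, "sex", k_range = 10, plan = cv_plan(5, 3, r),
                         models = "enet_lr")
    strata <- tibble::tibble(recording_id = fe$recording_id,
                             degraded = fe$recording_id %in% flagged,
                             clean = !(fe$recording_id %in% flagged))
    sm <- stratum_metrics(sw, strata, k = 10)
    isTRUE(sm$auc_roc[sm$stratum == "clean"] >
             sm$auc_roc[sm$stratum == "degraded"])
  }, logical(1))
  expect_gte(sum(ok), 5)
})

test_that("a full-cohort subgroup rerun is the pooled run", {
  fe <- toy_features(n = 50, p_noise = 9, seed = 8)
  fe$site <- "india"
  pooled <- make_sweep(fe)
  sub <- subgroup_rerun(fe, "outcome", site = "india", k_range = 5,
                        plan = cv_plan(5, 3, 2), models = "enet_lr",
                        nrounds = 20)
  expect_identical(pooled$results$auc_roc, sub$results$auc_roc)
  expect_identical(pooled$predictions$probability, sub$predictions$probability)
})

test_that("disjoint subgroups are evaluated on disjoint samples", {
  fe <- toy_features(n = 60, p_noise = 9, seed = 9)
  fe$site <- rep(c("india", "thailand"), each = 30)
  a <- subgroup_rerun(fe, "outcome", site = "india", k_range = 3,
                      plan = cv_plan(3, 1, 2), models = "enet_lr", nrounds = 10)
  b <- subgroup_rerun(fe, "outcome", site = "thailand", k_range = 3,
                      plan = cv_plan(3, 1, 2), models = "enet_lr", nrounds = 10)
  expect_length(intersect(a$predictions$recording_id,
                          b$predictions$recording_id), 0)
})

test_that("individual ranking is threshold-free, stable, and bounded", {
  fe <- toy_features(n = 30, p_noise = 5, seed = 10)
  sw <- make_sweep(fe, reps = 4)
  ind <- rank_individuals(sw, n_top = 10, k = 5)
  expect_length(intersect(ind$best$recording_id, ind$worst$recording_id), 0)
  expect_true(all(ind$best$mean_correct_class_probability >= 0 &
                    ind$best$mean_correct_class_probability <= 1))
  expect_true(all(ind$best$n_predictions == 4))
  # stable under prediction-row reordering
  sw_shuf <- sw
  set.seed(1)
  sw_shuf$predictions <- sw$predictions[sample(nrow(sw$predictions)), ]
  ind2 <- rank_individuals(sw_shuf, n_top = 10, k = 5)
  expect_identical(ind$best, ind2$best)
  expect_warning(rank_individuals(sw, n_top = 50, k = 5), "truncating")
})

test_that("atypical individuals surface in the worst-predicted list", {
  flagged <- sprintf("rec%04d", (1:5) * 7)
  hits <- vapply(1:6, function(r) {
    co <- atypical_cohort(50, (1:5) * 7, r)
    fe <- extract_cohort_features(co)
    sw <- run_topk_sweep(fe, "sex", k_range = 10, plan = cv_plan(5, 5, r),
                         models = "enet_lr")
    worst <- rank_individuals(sw, 10, k = 10)$worst
    sum(flagged %in% worst$recording_id)
  }, numeric(1))
  expect_gte(sum(hits >= 3), 3)
})

test_that("selection frequencies obey the counting identities", {
  fe <- toy_features(n = 40, p_noise = 7, seed = 12)
  sw <- run_topk_sweep(fe, "outcome", k_range = c(5, 8), plan = cv_plan(4, 2, 3),
                       models = "enet_lr", nrounds = 10)
  f5 <- selection_frequency(sw, 5)
  expect_equal(sum(f5$frequency), 5)            # sums to k
  f8 <- selection_frequency(sw, 8)
  expect_true(all(f8$frequency == 1))           # k = n_features -> all selected
  expect_identical(nrow(f5), 8L)                # zeros kept
})

test_that("the injected signal feature is selected almost always at k = 5", {
  fe <- toy_features(n = 200, p_noise = 49, seed = 14)
  sw <- run_topk_sweep(fe, "outcome", k_range = 5, plan = cv_plan(5, 4, 7),
                       models = "enet_lr", nrounds = 10)
  freq <- selection_frequency(sw, 5)
  expect_gte(freq$frequency[freq$feature == "signal"], 0.9)
})

test_that("feature distributions summarise classes and flag degeneracy", {
  fe <- toy_features(n = 60, p_noise = 3, seed = 15)
  fd <- feature_distributions(fe, "outcome", c("signal", "noise01"))
  expect_identical(nrow(fd), 4L)
  expect_gt(abs(fd$smd[fd$feature == "signal"][1]),
            abs(fd$smd[fd$feature == "noise01"][1]))
  # permutation invariance
  fd2 <- feature_distributions(fe[sample(nrow(fe)), ], "outcome",
                               c("signal", "noise01"))
  expect_equal(fd$mean, fd2$mean)
  # feature equal to the label -> infinite separation, flagged
  fe$copy <- as.numeric(fe$outcome == "b")
  fdc <- feature_distributions(fe, "outcome", "copy")
  expect_true(all(is.infinite(fdc$smd)))
  expect_error(feature_distributions(fe, "outcome", "nope"),
               class = "gait_validation_error")
})

test_that("null-world standardized mean differences stay small", {
  fe <- toy_features(n = 150, p_noise = 10, seed = 16)
  fe$signal <- rnorm(150)   # remove the real effect
  fd <- feature_distributions(fe, "outcome",
                              c("signal", sprintf("noise%02d", 1:10)))
  # 3 SE of the null SMD at n = 150 (SE ~ sqrt(4/n) ~ 0.163)
  expect_true(all(abs(fd$smd) < 3 * sqrt(4 / 150)))
})
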