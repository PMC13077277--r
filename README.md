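# gaitpipe

Markerless gait analysis from smartphone video, without the video: an R
package that turns 2D pose-landmark time series (the 33-landmark output of a
full-body pose estimator, 30 Hz) into sex and age-group classification, with
a leakage-guarded evaluation framework and a synthetic kinematic walker so
every stage is testable without data downloads.

It is written for researchers prototyping low-cost gait phenotyping
pipelines — people who have (or plan to collect) walking videos in primary
care or community settings and want the analysis chain, not the camera
work.

## What it computes

**Gait cycles from ankle crossings.** The per-frame Euclidean distance
between the left and right ankle landmarks, `d(t) = ‖ankle_L(t) −
ankle_R(t)‖`, is minimal twice per stride. A gait cycle is the span of three
consecutive prominent local minima of `d(t)`; only the **second** cycle is
analysed, avoiding edge effects. Recordings whose minima are too few or too
irregular (non-gait pose failures) are counted as infeasible — the
feasibility proportion is itself a reported outcome.

**A 109-dimensional feature vector.** Over the second cycle: 15 joint-pair
distances (rescaled to meters by an in-video reference object of known
length) and 12 interior joint angles `∠(A, vertex, B) = arccos(u·w / ‖u‖‖w‖)`
per frame, each summarised by mean, SD, skewness `m₃/m₂^{3/2}` and excess
kurtosis `m₄/m₂² − 3` (population moments), plus the cycle frame count as a
walking-speed surrogate: 15·4 + 12·4 + 1 = 109.

**Leakage-guarded repeated stratified CV.** 5 folds × 20 repetitions = 100
train–test evaluations per configuration. Within each training fold only:
z-scaling, elastic-net logistic regression with balanced class weights,
feature ranking by |coefficient|, top-k selection (k = 1..50), then an
elastic-net classifier and a histogram gradient-boosting classifier predict
the held-out fold. Metrics: AUC-ROC (Mann–Whitney with tie credit),
accuracy, per-class sensitivity and F1, and MCC — aggregated into
performance-vs-k curves, plus five sensitivity analyses (BMI strata, site
re-runs, best/worst individuals, selection frequencies, per-class feature
distributions).

**A synthetic cohort generator.** A sagittal-plane kinematic walker with
tunable sex effects (shoulder/hip ratio, stature, arm swing), age effects
(cadence, step length, stride-timing noise), landmark jitter, and a
configurable rate of garbage recordings emulating pose-estimation failure.
`effect_scale = 0` produces an exact null world.

## Worked example

```r
library(gaitpipe)
library(dplyr)

cohort   <- sample_cohort(80, noise = noise_config(failure_rate = 0.065),
                          rng_seed = 11)
segments <- segment_cohort(cohort)
feasibility(segments)
#> # A tibble: 1 × 3
#>   n_success n_total proportion
#>       <int>   <int>      <dbl>
#> 1        75      80      0.938

features <- extract_cohort_features(cohort, segments)
sweep <- run_topk_sweep(features, "sex", k_range = c(5, 15),
                        plan = cv_plan(5, 5, base_seed = 11))
aggregate_curves(sweep) |> filter(metric == "auc_roc")
#> # A tibble: 4 × 6
#>   model       k metric   mean     sd     n
#>   <chr>   <dbl> <chr>   <dbl>  <dbl> <int>
#> 1 enet_lr     5 auc_roc 0.883 0.0938    25
#> 2 enet_lr    15 auc_roc 0.903 0.0887    25
#> 3 hist_gb     5 auc_roc 0.875 0.0904    25
#> 4 hist_gb    15 auc_roc 0.901 0.0897    25

selection_frequency(sweep, 15) |> head(3)
#> # A tibble: 3 × 3
#>   feature                             n_selected frequency
#>   <chr>                                    <int>     <dbl>
#> 1 d_left_shoulder_right_shoulder_mean         25      1
#> 2 d_right_shoulder_right_hip_mean             25      1
#> 3 d_right_elbow_right_shoulder_mean           22      0.88
```

Reading the output: 75 of 80 synthetic recordings yielded a usable second
gait cycle (93.8% feasibility — the five failures are injected
pose-estimation garbage the segmenter must reject). Sex classification
reaches a mean AUC of ~0.90 at 15 features, and the features the ranker
keeps selecting are exactly the morphological ones the generator encodes a
sex effect into (shoulder width, trunk edge lengths). `glance(sweep)`,
`tidy(sweep)` and `autoplot(sweep)` give the one-row summary, the
per-evaluation tibble, and the performance-vs-k plot; `run_pipeline()` runs
the whole chain (simulate → segment → extract → evaluate → sensitivity)
into a directory of fixed-format CSVs with a hashed manifest.

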