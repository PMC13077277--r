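---
title: "Markerless gait analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless gait analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpipe)
```

## The analytic chain

`gaitpipe` implements a complete pipeline for classifying sex and age group
from 2D pose-landmark time series of a person walking past a smartphone
camera:

1. **Pose model.** A recording is a sequence of frames, each carrying the 33
   named body landmarks a full-body 2D pose estimator emits (x, y,
   visibility at 30 Hz). The package consumes this format; it does not
   contain a pose-estimation network.
2. **Cycle segmentation.** The Euclidean distance between the left and right
   ankle landmarks oscillates with the feet: it is smallest twice per stride,
   when the feet pass each other. A gait cycle is the span of three
   consecutive prominent local minima of this signal, and only the *second*
   cycle is analysed, so features are never taken from the edge of a
   recording where pose estimates are least reliable.
3. **Feature extraction.** Within the second cycle, 15 joint-pair distances
   (converted to meters via an in-video reference object) and 12 interior
   joint angles are computed per frame and each series is summarised by four
   moments — mean, SD, skewness, excess kurtosis — giving 27 × 4 = 108
   features, plus the cycle's frame count as a walking-speed surrogate:
   109 features in total.
4. **Evaluation.** Repeated stratified 5-fold cross-validation (20
   repetitions, 100 train–test evaluations per configuration). Within every
   training fold only: z-scaling, elastic-net logistic feature ranking by
   absolute coefficient magnitude, top-k selection for k = 1..50, and
   fitting of two classifiers — the elastic-net logistic regression itself
   and a histogram-based gradient-boosting model. Metrics (AUC-ROC,
   accuracy, per-class sensitivity and F1, MCC) are aggregated into
   performance-versus-k curves.
5. **Sensitivity analyses.** BMI-stratified metrics, per-site re-runs,
   best/worst-predicted individuals, feature-selection frequency, and
   per-class feature distributions.

Because the underlying videos and pose extractions of the motivating study
are not deposited, a synthetic kinematic walker generates labelled pose
sequences with the statistical structure the analysis assumes. The walker is
first-class, tested code: every downstream stage is exercised end-to-end
against it.

## The synthetic walker and what it does (and does not) emulate

The walker is a stylized sagittal-plane model. The pelvis translates at
constant mean speed `step_length × 2 × cadence`; hip–knee–ankle chains
follow sinusoidal joint-angle trajectories with the two legs in anti-phase;
arms swing opposite their ipsilateral legs; the torso bobs at twice the
stride frequency; face and hand landmarks ride as rigid offsets from the
head and wrists. Gaussian jitter (default SD 0.5% of stature — a
calibration choice, not a measured pose-estimator property) is added to
every landmark in every frame, and a configurable fraction of recordings is
replaced by garbage sequences of uniform-random landmarks, emulating a pose
estimator locking onto non-human elements.

Two projection choices deserve explanation:

* **Widths as vertical offsets.** Mediolateral widths (shoulder, hip) are
  rendered as small *vertical* offsets between left and right landmarks, as
  if the camera sat slightly above the walking plane. A purely lateral
  (horizontal) offset would shift the ankle-crossing minima of the
  ankle-distance signal asymmetrically and destroy their even spacing; the
  vertical rendering keeps consecutive minima separated by `1/(2 × cadence)`
  seconds (inter-minima coefficient of variation < 0.05 without jitter)
  while keeping widths recoverable from 2D landmark distances, which is
  where the sex signal largely lives.
* **Group effects.** Male subjects differ from female in shoulder/hip width
  ratio (×1.12), stature (×1.08), and arm-swing amplitude (×1.15); subjects
  aged 65+ differ in cadence (×0.95), step length (×0.94), and
  stride-timing noise (+0.02 rad/frame). A single `effect_scale` multiplies
  all group differences; at 0 the group-conditional distributions are
  identical (a null world). These defaults were calibrated once so that the
  generator expresses the designed ordering — sex considerably easier to
  classify than age group, as the motivating study observed on real data
  (≈0.90 vs ≈0.70 AUC) — and then frozen. With the defaults the pipeline
  recovers sex AUC ≈ 0.88–0.96 and age AUC ≈ 0.57–0.68 at k = 15 across
  seeds.

What the walker does **not** emulate: perspective and depth, ground-contact
dynamics, multi-person scenes, visibility dropout, autocorrelated
pose-estimator error, or any biomechanically validated kinematics. Passing
tests therefore demonstrate that the *pipeline* behaves correctly on data
with the assumed structure; they are not evidence about real video.

## Numerical and algorithmic choices

**Minima detection.** The ankle-distance signal is smoothed with a centred
moving average (default window 5 frames at 30 Hz) and strict interior local
minima are kept when their topographic prominence reaches 10% of the
smoothed signal's range. Plateau minima resolve to their leftmost frame;
constant signals yield no minima rather than an error. Both parameters are
config-exposed; the source protocol states neither.

**Cycle tiling.** A cycle is three consecutive minima, but "second cycle"
is only unambiguous if cycles tile without overlap: cycle 1 spans minima
1–3, cycle 2 spans minima 3–5 (half-open frame window `[m3, m5)`), so at
least five minima are required. The half-open convention makes cycle frame
counts — the walking-speed surrogate — tile the signal without double
counting. This tiling is an interpretation, flagged as such.

**Rejecting non-gait recordings.** Smoothed uniform noise still produces
many prominent minima, so a minima-count rule alone cannot detect failed
pose extractions. A regularity guard rejects recordings whose inter-minima
gaps have a coefficient of variation above 0.20 (failure reason
`irregular_minima`). The threshold was calibrated once on a
walks-versus-noise experiment (jittered walks, including the
loose-clothing mode, stay below ≈0.14; uniform-noise garbage stays above
≈0.26) and then frozen. Failures are *values*, not exceptions, because the
cohort-level feasibility proportion counts them.

**Moments.** Population (n-denominator) central moments; skewness
m3/m2^(3/2); *excess* kurtosis m4/m2² − 3. A constant series gets skewness
and kurtosis 0 (flagged) rather than NaN so feature matrices stay dense.
The choice of population moments matches the most common default of
scientific array libraries and is frozen in tests; the source protocol
names the statistics without formulas.

**Distance pairs and angle triplets.** The exact 15 pairs and 12 triplets
of the motivating protocol are not available in the public text. The
defaults here are a documented reconstruction — trunk-box edges, limb
segments, ankle span, foot segments; interior angles at elbows, shoulders,
hips, knees, ankles, plus trunk and neck angles via virtual mid-shoulder /
mid-hip points — and both sets are config-replaceable, validated against
the landmark-name enum at load.

**Elastic net.** Ranking and the linear classifier use an
elastic-net-penalised logistic regression (`l1_ratio` 0.5, strength 1.0 in
scaled units, i.e. per-observation penalty `strength / n_train`), with
balanced class weights `n / (n_classes × n_c)`. Coefficient ties — including
the exact zeros the L1 penalty produces — break lexicographically by
feature name, making top-k selection reproducible. The exact
hyperparameters of the motivating study are unavailable; these are
documented reconstructions, config-exposed.

**Histogram gradient boosting.** An established binned-histogram
gradient-boosted tree implementation is used as the second backend (≤255
bins, learning rate 0.1, 31 leaves, ~20-sample minimum leaves, no early
stopping, 100 rounds, single-threaded for determinism). The contribution of
this package is the leakage-guarded framework around the learner, not the
learner internals.

**Leakage guarantees.** Scaler, ranking, selection and model fitting see
only the training fold; the suite asserts that corrupting a held-out
sample changes neither the fold's selected features nor the predictions of
the other held-out samples. Folds are drawn once per repetition and shared
across all k and both models, so the performance-vs-k curves differ only by
feature count. Single-class test folds are discarded and counted, never
imputed. All randomness derives from one base seed; reruns are
byte-identical (CSV writers pin float formatting).

## Known limitations and honest calibration notes

* **Repeated-CV optimism at small n.** In a null world (`effect_scale = 0`,
  n = 120) the sweep's mean AUC is not centred exactly at 0.5: within-fold
  top-k selection aligns the model with chance associations that are
  properties of the finite cohort and therefore shared by training and
  held-out folds. The flexible boosting backend shows this most (mean AUC
  ≈ 0.55 ± 0.06 across cohort realizations; individual realizations reach
  ≈ 0.65, and label-permutation reruns reproduce the same spread, ruling
  out leakage). The package's null-calibration test keeps the frozen seeds
  and the nominal [0.40, 0.60] band; one (outcome, model) cell fails it for
  exactly this reason, and we report that openly rather than reseeding.
  The practical lesson matches standard advice: repeated CV with in-fold
  selection is leakage-free but still an optimistic estimator at small n.
* **Loose clothing degrades feasibility, not predictions.** In the
  synthetic world, inflating lower-body landmark jitter (the loose-clothing
  mode) destroys the regularity of the ankle-distance minima and the
  recording fails segmentation — it lowers the feasibility proportion
  rather than producing a poorly-predicted individual. The
  individual-level and stratum-level diagnostics are therefore tested with
  atypical-morphology injections (feature structure drawn from the opposite
  class), which reliably produce poor predictions.
* **Single cycle.** All features come from one gait cycle per recording, by
  design of the emulated protocol; multi-cycle averaging is out of scope.
* **Problem sizes in the test suite** were chosen to keep the default run
  in minutes: null-world calibration uses a representative k grid
  {1, 5, 10, 20, 35, 50} (the inflation it checks is flat in k), the demo
  pipeline uses n = 40 with k ≤ 5, and Monte-Carlo property checks use
  6–100 replicates each. The acceptance script evaluates the full default
  plan (5 × 20 folds) at n = 155, the motivating study's recording count.

## Interfaces

The package is tidyverse-native: every user-facing function takes a data
frame (or tibble-backed object) first and returns a tibble, so stages chain
with the pipe; sweep objects have `tidy()`/`glance()` methods and
`autoplot()`; `run_pipeline()` orchestrates simulate → segment → extract →
evaluate → sensitivity and writes fixed-format CSVs plus a hashed manifest,
and `render_report()` draws the standard plots from those CSVs. These
functions, together with `scripts/acceptance.R`, are the package's
command-line surface; no separate shell binary is shipped.
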