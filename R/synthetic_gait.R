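# Synthetic kinematic walker: labelled pose sequences with the statistical
# structure the downstream analysis assumes (sex/age effects on morphology
# and gait timing, landmark jitter, occasional detection failures).
#
# The walker is a stylized sagittal-plane (side-view) model: the pelvis
# translates at constant mean velocity, hip-knee-ankle chains are driven by
# sinusoidal joint angles in anti-phase, arms swing opposite their
# ipsilateral legs, the torso bobs at twice the stride frequency, and face /
# hand landmarks ride as rigid offsets from head / wrist anchors.
# Mediolateral body widths (shoulder, hip) are rendered as small *vertical*
# offsets between left and right landmarks, as if the camera sat slightly
# above the walking plane: widths stay recoverable from 2D landmark
# distances while the ankle-to-ankle distance signal keeps evenly spaced
# minima, which the cycle detector relies on.

#' Group-effect configuration for the synthetic cohort
#'
#' Multiplicative shifts applied to male subjects (relative to female) and to
#' subjects aged 65+ (relative to younger), plus one additive shift on
#' stride-timing noise. `effect_scale` scales every group difference:
#' multiplicative factors are raised to `effect_scale` and the additive term
#' is multiplied by it, so at `effect_scale = 0` the group-conditional
#' parameter distributions are identical (a null world).
#'
#' @param sex_shoulder_hip_ratio male shoulder-to-hip width ratio factor.
#' @param sex_stature male stature factor.
#' @param sex_arm_swing male arm-swing amplitude factor.
#' @param age_cadence cadence factor for 65+ (slower when < 1).
#' @param age_step_length step-length factor for 65+.
#' @param age_phase_jitter additive shift (radians/frame) on stride-phase
#'   random-walk noise for 65+.
#' @param effect_scale nonnegative scale on all group differences.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(sex_shoulder_hip_ratio = 1.12,
                          sex_stature = 1.08,
                          sex_arm_swing = 1.15,
                          age_cadence = 0.95,
                          age_step_length = 0.94,
                          age_phase_jitter = 0.02,
                          effect_scale = 1) {
  assert_scalar_num(effect_scale, "effect_scale", nonneg = TRUE)
  for (nm in c("sex_shoulder_hip_ratio", "sex_stature", "sex_arm_swing",
               "age_cadence", "age_step_length")) {
    assert_scalar_num(get(nm), nm, positive = TRUE)
  }
  structure(list(sex_shoulder_hip_ratio = sex_shoulder_hip_ratio,
                 sex_stature = sex_stature,
                 sex_arm_swing = sex_arm_swing,
                 age_cadence = age_cadence,
                 age_step_length = age_step_length,
                 age_phase_jitter = age_phase_jitter,
                 effect_scale = effect_scale),
            class = "effect_config")
}

#' Landmark-noise configuration
#'
#' @param jitter_sd_px per-landmark Gaussian jitter SD in pixels; `NA` means
#'   0.5% of the subject's stature (a calibration choice, not a measured
#'   pose-estimator property).
#' @param loose_clothing_mode when `TRUE`, jitter on hip, knee and ankle
#'   landmarks is inflated by `loose_factor` (emulating drape of loose
#'   clothing over the lower body).
#' @param loose_factor jitter inflation factor for `loose_clothing_mode`.
#' @param failure_rate probability that a recording is replaced by a
#'   non-walking garbage sequence (uniform random landmarks), emulating pose
#'   estimation locking onto non-human elements. Garbage recordings are not
#'   flagged; downstream segmentation must detect them.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(jitter_sd_px = NA, loose_clothing_mode = FALSE,
                         loose_factor = 3, failure_rate = 0) {
  if (!is.na(jitter_sd_px)) assert_scalar_num(jitter_sd_px, "jitter_sd_px", nonneg = TRUE)
  assert_scalar_num(failure_rate, "failure_rate", nonneg = TRUE)
  if (failure_rate > 1) abort_gait("failure_rate must lie in [0, 1]", "gait_validation_error")
  structure(list(jitter_sd_px = jitter_sd_px,
                 loose_clothing_mode = isTRUE(loose_clothing_mode),
                 loose_factor = loose_factor,
                 failure_rate = failure_rate),
            class = "noise_config")
}

#' Draw subject morphology and gait parameters
#'
#' Samples one subject's body segment lengths (pixels) and gait-timing
#' parameters from log-normal distributions whose group means are shifted
#' according to the effect configuration. Deterministic given the seed.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_group `"under65"` or `"over65eq"`.
#' @param effects an [effect_config()].
#' @param rng_seed integer seed.
#' @return A one-row tibble of subject parameters (class `subject_params`).
#' @export
sample_subject <- function(sex = c("female", "male"),
                           age_group = c("under65", "over65eq"),
                           effects = effect_config(), rng_seed = 1) {
  sex <- match.arg(sex)
  age_group <- match.arg(age_group)
  stopifnot(inherits(effects, "effect_config"))
  es <- effects$effect_scale
  male <- sex == "male"
  old <- age_group == "over65eq"
  f_stature <- if (male) effects$sex_stature^es else 1
  f_ratio <- if (male) effects$sex_shoulder_hip_ratio^es else 1
  f_arm <- if (male) effects$sex_arm_swing^es else 1
  f_cad <- if (old) effects$age_cadence^es else 1
  f_step <- if (old) effects$age_step_length^es else 1
  a_jit <- if (old) effects$age_phase_jitter * es else 0

  with_seed(rng_seed, {
    ln <- function(mean, sdlog) mean * exp(stats::rnorm(1, 0, sdlog))
    stature <- ln(320 * f_stature, 0.045)           # female baseline 320 px (~1.6 m)
    subject <- tibble::tibble(
      stature_px       = stature,
      shoulder_width_px = ln(0.235 * stature * sqrt(f_ratio), 0.05),
      hip_width_px     = ln(0.200 * stature / sqrt(f_ratio), 0.05),
      upper_arm_px     = ln(0.172 * stature, 0.03),
      forearm_px       = ln(0.157 * stature, 0.03),
      thigh_px         = ln(0.245 * stature, 0.03),
      shank_px         = ln(0.246 * stature, 0.03),
      foot_px          = ln(0.152 * stature, 0.03),
      head_offset_px   = ln(0.130 * stature, 0.03),
      cadence_hz       = ln(0.92 * f_cad, 0.08),     # strides per second
      step_length_px   = ln(0.42 * stature / f_stature * f_step, 0.09),
      arm_swing_amp_rad = ln(0.30 * f_arm, 0.15),
      knee_flex_amp_rad = ln(0.60, 0.10),
      torso_bob_amp_px = ln(0.015 * stature, 0.20),
      phase_jitter_sd  = 0.010 + a_jit
    )
    class(subject) <- c("subject_params", class(subject))
    subject
  })
}

# rigid offsets of face landmarks from the head centre, and hand landmarks
# from the wrist, in units of head_offset / forearm length respectively.
face_offsets <- function(h) {
  tibble::tibble(
    name = c("nose", "left_eye_inner", "left_eye", "left_eye_outer",
             "right_eye_inner", "right_eye", "right_eye_outer",
             "left_ear", "right_ear", "mouth_left", "mouth_right"),
    dx = h * c(0.30, 0.22, 0.20, 0.18, 0.22, 0.20, 0.18, -0.05, -0.05, 0.24, 0.24),
    dy = h * c(0.05, -0.08, -0.08, -0.08, -0.08, -0.08, -0.08, 0.00, 0.00, 0.16, 0.16) +
      h * c(0, 0.03, 0.03, 0.03, -0.03, -0.03, -0.03, 0.04, -0.04, 0.03, -0.03)
  )
}

hand_offsets <- function(fa, side_sign) {
  tibble::tibble(
    name = paste0(c("left_", "right_")[(side_sign < 0) + 1L],
                  c("pinky", "index", "thumb")),
    dx = fa * c(0.22, 0.25, 0.15),
    dy = fa * c(0.10, 0.08, 0.02) + side_sign * fa * 0.02
  )
}

#' Generate a synthetic walking pose sequence
#'
#' Renders a side-view kinematic walker for `n_strides` strides at the given
#' frame rate, in pixel space, with additive Gaussian landmark jitter. All 33
#' landmarks are present in every frame. With zero jitter and zero phase
#' noise the ankle-to-ankle distance signal is periodic with consecutive
#' minima separated by `1 / (2 * cadence)` seconds.
#'
#' @param subject a `subject_params` row from [sample_subject()].
#' @param n_strides number of strides to render (>= 3, so that a second gait
#'   cycle exists).
#' @param frame_rate_hz frames per second (default 30).
#' @param noise a [noise_config()]. `failure_rate` is ignored here (it acts
#'   at cohort level); jitter settings apply.
#' @param rng_seed integer seed for jitter and phase noise.
#' @return A pixel-space [pose_sequence()].
#' @export
generate_walk <- function(subject, n_strides = 5, frame_rate_hz = 30,
                          noise = noise_config(), rng_seed = 1) {
  stopifnot(inherits(subject, "subject_params"))
  if (n_strides < 3) {
    abort_gait("n_strides must be >= 3 so a second gait cycle exists",
               "gait_validation_error")
  }
  assert_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  p <- as.list(subject)
  fps <- frame_rate_hz
  duration <- n_strides / p$cadence_hz
  nf <- max(2L, as.integer(round(duration * fps)))
  t <- (seq_len(nf) - 1) / fps
  speed <- p$step_length_px * 2 * p$cadence_hz
  leg <- p$thigh_px + p$shank_px
  trunk <- 0.30 * p$stature_px
  x0 <- 150
  ground_y <- 650

  with_seed(rng_seed, {
    omega <- 2 * pi * p$cadence_hz
    phase <- omega * t
    if (p$phase_jitter_sd > 0) {
      phase <- phase + cumsum(stats::rnorm(nf, 0, p$phase_jitter_sd))
    }
    pelvis_x <- x0 + speed * t
    pelvis_y <- ground_y - 0.98 * leg + p$torso_bob_amp_px * cos(2 * phase)
    a_hip <- asin(min(0.95, p$step_length_px / (2 * leg)))

    leg_chain <- function(side_phase, hip_dy) {
      alpha <- a_hip * sin(phase + side_phase)
      kflex <- p$knee_flex_amp_rad * (1 - cos(phase + side_phase)) / 2
      hip <- cbind(pelvis_x, pelvis_y + hip_dy)
      knee <- hip + cbind(p$thigh_px * sin(alpha), p$thigh_px * cos(alpha))
      ankle <- knee + cbind(p$shank_px * sin(alpha - kflex),
                            p$shank_px * cos(alpha - kflex))
      list(hip = hip, knee = knee, ankle = ankle)
    }
    arm_chain <- function(side_phase, sh_dy) {
      gamma <- p$arm_swing_amp_rad * sin(phase + side_phase + pi)
      shoulder <- cbind(pelvis_x, pelvis_y - trunk + sh_dy)
      elbow <- shoulder + cbind(p$upper_arm_px * sin(gamma),
                                p$upper_arm_px * cos(gamma))
      wrist <- elbow + cbind(p$forearm_px * sin(gamma + 0.40),
                             p$forearm_px * cos(gamma + 0.40))
      list(shoulder = shoulder, elbow = elbow, wrist = wrist)
    }

    # left landmarks sit width/2 below their right counterparts (slightly
    # elevated camera): widths survive projection, ankle minima stay regular
    hw <- p$hip_width_px / 2
    sw <- p$shoulder_width_px / 2
    lleg <- leg_chain(0, +hw)
    rleg <- leg_chain(pi, -hw)
    larm <- arm_chain(0, +sw)
    rarm <- arm_chain(pi, -sw)
    head_c <- cbind(pelvis_x, pelvis_y - trunk - p$head_offset_px)

    pts <- vector("list", 33L)
    names(pts) <- landmark_names()
    fo <- face_offsets(p$head_offset_px)
    for (i in seq_len(nrow(fo))) {
      pts[[fo$name[i]]] <- cbind(head_c[, 1] + fo$dx[i], head_c[, 2] + fo$dy[i])
    }
    pts$left_shoulder <- larm$shoulder; pts$right_shoulder <- rarm$shoulder
    pts$left_elbow <- larm$elbow;       pts$right_elbow <- rarm$elbow
    pts$left_wrist <- larm$wrist;       pts$right_wrist <- rarm$wrist
    for (side in c("left", "right")) {
      arm <- if (side == "left") larm else rarm
      ho <- hand_offsets(p$forearm_px, if (side == "left") 1 else -1)
      for (i in seq_len(nrow(ho))) {
        pts[[ho$name[i]]] <- cbind(arm$wrist[, 1] + ho$dx[i],
                                   arm$wrist[, 2] + ho$dy[i])
      }
    }
    pts$left_hip <- lleg$hip;   pts$right_hip <- rleg$hip
    pts$left_knee <- lleg$knee; pts$right_knee <- rleg$knee
    pts$left_ankle <- lleg$ankle; pts$right_ankle <- rleg$ankle
    foot <- p$foot_px
    for (side in c("left", "right")) {
      ankle <- pts[[paste0(side, "_ankle")]]
      pts[[paste0(side, "_heel")]] <- cbind(ankle[, 1] - 0.30 * foot,
                                            ankle[, 2] + 0.15 * foot)
      pts[[paste0(side, "_foot_index")]] <- cbind(ankle[, 1] + 0.70 * foot,
                                                  ankle[, 2] + 0.15 * foot)
    }

    xs <- do.call(cbind, lapply(pts[landmark_names()], function(m) m[, 1]))
    ys <- do.call(cbind, lapply(pts[landmark_names()], function(m) m[, 2]))

    sd_px <- if (is.na(noise$jitter_sd_px)) 0.005 * p$stature_px else noise$jitter_sd_px
    if (sd_px > 0) {
      sds <- rep(sd_px, 33L)
      if (noise$loose_clothing_mode) {
        lower <- landmark_index(c("left_hip", "right_hip", "left_knee",
                                  "right_knee", "left_ankle", "right_ankle")) + 1L
        sds[lower] <- sds[lower] * noise$loose_factor
      }
      sdm <- matrix(sds, nrow = nf, ncol = 33L, byrow = TRUE)
      xs <- xs + stats::rnorm(nf * 33L, 0, 1) * sdm
      ys <- ys + stats::rnorm(nf * 33L, 0, 1) * sdm
    }

    width <- ceiling(max(xs) + 100)
    height <- 720
    df <- tibble::tibble(
      frame = rep(0:(nf - 1L), each = 33L),
      landmark = rep(0:32, times = nf),
      x = as.vector(t(xs)),
      y = as.vector(t(ys)),
      visibility = 1
    )
    pose_sequence(df, frame_rate_hz = fps, coordinate_space = "pixel",
                  image_width_px = width, image_height_px = height)
  })
}

#' Generate a garbage (failed-detection) pose sequence
#'
#' Uniform random landmark positions in the image, emulating a pose estimator
#' locking onto non-human elements. Used as the cohort failure mode.
#'
#' @param n_frames_out number of frames.
#' @param frame_rate_hz frames per second.
#' @param image_width_px,image_height_px image size.
#' @param rng_seed integer seed.
#' @return A pixel-space [pose_sequence()].
#' @export
generate_garbage <- function(n_frames_out, frame_rate_hz = 30,
                             image_width_px = 1280, image_height_px = 720,
                             rng_seed = 1) {
  with_seed(rng_seed, {
    nf <- as.integer(n_frames_out)
    df <- tibble::tibble(
      frame = rep(0:(nf - 1L), each = 33L),
      landmark = rep(0:32, times = nf),
      x = stats::runif(nf * 33L, 0, image_width_px),
      y = stats::runif(nf * 33L, 0, image_height_px),
      visibility = stats::runif(nf * 33L, 0.2, 1)
    )
    pose_sequence(df, frame_rate_hz = frame_rate_hz, coordinate_space = "pixel",
                  image_width_px = image_width_px, image_height_px = image_height_px)
  })
}

largest_remainder <- function(fracs, n) {
  raw <- fracs * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Sample a labelled synthetic cohort
#'
#' Draws `n` recordings with sex / age-group / site labels matching the
#' requested fractions exactly (largest-remainder rounding), renders a walk
#' per subject, and replaces a `failure_rate` fraction (Bernoulli per
#' recording) with garbage sequences that carry no flag — downstream cycle
#' segmentation must detect them. BMI is drawn log-normally with a
#' configurable coupling to the subject's hip width.
#'
#' @param n cohort size (>= 2).
#' @param sex_female_frac,age_over65_frac label fractions in (0, 1); defaults
#'   mirror the study cohort (64.8% female, 37.9% aged 65+).
#' @param effects an [effect_config()].
#' @param noise a [noise_config()]; its `failure_rate` acts here.
#' @param site_mix named fractions for `thailand` / `india` (defaults 35.2% /
#'   64.8%).
#' @param n_strides strides per recording.
#' @param frame_rate_hz frames per second.
#' @param bmi_coupling exponent linking BMI to relative hip width.
#' @param loose_clothing_ids optional recording indices forced into
#'   loose-clothing jitter mode (for degradation experiments).
#' @param rng_seed integer seed.
#' @return A tibble with one row per recording: `recording_id`, label and
#'   covariate columns, `is_garbage` (ground truth, for diagnostics only) and
#'   a `pose` list-column of [pose_sequence()] objects.
#' @export
sample_cohort <- function(n, sex_female_frac = 0.648, age_over65_frac = 0.379,
                          effects = effect_config(), noise = noise_config(),
                          site_mix = c(thailand = 0.352, india = 0.648),
                          n_strides = 5, frame_rate_hz = 30,
                          bmi_coupling = 1, loose_clothing_ids = integer(),
                          rng_seed = 1) {
  if (n < 2) abort_gait("cohort size must be >= 2", "gait_validation_error")
  if (sex_female_frac <= 0 || sex_female_frac >= 1 ||
      age_over65_frac <= 0 || age_over65_frac >= 1) {
    abort_gait("label fractions must lie in (0, 1)", "gait_validation_error")
  }
  counts_sex <- largest_remainder(c(sex_female_frac, 1 - sex_female_frac), n)
  counts_age <- largest_remainder(c(age_over65_frac, 1 - age_over65_frac), n)
  counts_site <- largest_remainder(c(site_mix[["thailand"]], site_mix[["india"]]), n)

  with_seed(derive_seed(rng_seed, 1), {
    sex <- sample(rep(c("female", "male"), counts_sex))
    age_group <- sample(rep(c("over65eq", "under65"), counts_age))
    site <- sample(rep(c("thailand", "india"), counts_site))
    age_years <- ifelse(age_group == "over65eq",
                        stats::runif(n, 65, 88), stats::runif(n, 25, 64.9))
    garbage <- stats::runif(n) < noise$failure_rate
  })

  rows <- purrr::map(seq_len(n), function(i) {
    subj <- sample_subject(sex[i], age_group[i], effects,
                           rng_seed = derive_seed(rng_seed, 2, i))
    nz <- noise
    if (i %in% loose_clothing_ids) nz$loose_clothing_mode <- TRUE
    if (garbage[i]) {
      nf <- as.integer(round(n_strides / subj$cadence_hz * frame_rate_hz))
      seq <- generate_garbage(nf, frame_rate_hz,
                              rng_seed = derive_seed(rng_seed, 3, i))
    } else {
      seq <- generate_walk(subj, n_strides = n_strides,
                           frame_rate_hz = frame_rate_hz, noise = nz,
                           rng_seed = derive_seed(rng_seed, 3, i))
    }
    rel_hip <- subj$hip_width_px / (0.200 * subj$stature_px)
    bmi <- with_seed(derive_seed(rng_seed, 4, i),
                     22.9 * rel_hip^bmi_coupling * exp(stats::rnorm(1, 0, 0.16)))
    ref_m <- if (site[i] == "thailand") 1.0 else 0.75
    ref_px <- ref_m / 0.005   # nominal 0.005 m per pixel at the walking plane
    tibble::tibble(
      recording_id = sprintf("rec%04d", i),
      sex = sex[i], age_years = age_years[i], age_group = age_group[i],
      bmi = bmi, site = site[i],
      reference_length_m = ref_m, reference_length_px = ref_px,
      is_garbage = garbage[i],
      pose = list(seq)
    )
  })
  dplyr::bind_rows(rows)
}
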