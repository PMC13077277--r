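# Shared fixtures and independent oracles, all built in code at test time.

# a pose sequence whose ankle-to-ankle distance equals `d` frame by frame:
# every landmark at the origin except the right ankle at (d, 0)
seq_from_distance <- function(d, frame_rate_hz = 30) {
  nf <- length(d)
  df <- tibble::tibble(
    frame = rep(0:(nf - 1L), each = 33L),
    landmark = rep(0:32, times = nf),
    x = 0, y = 0, visibility = 1
  )
  df$x[df$landmark == 28L] <- d[df$frame[df$landmark == 28L] + 1L]
  pose_sequence(df, frame_rate_hz = frame_rate_hz, coordinate_space = "pixel")
}

# a pose sequence from an explicit frames x 33 x 2 coordinate array
seq_from_coords <- function(xs, ys, frame_rate_hz = 30) {
  nf <- nrow(xs)
  pose_sequence(tibble::tibble(
    frame = rep(0:(nf - 1L), each = 33L),
    landmark = rep(0:32, times = nf),
    x = as.vector(t(xs)), y = as.vector(t(ys)), visibility = 1
  ), frame_rate_hz = frame_rate_hz, coordinate_space = "pixel")
}

# a quiet default walk for structural checks
fixture_walk <- function(seed = 1, n_strides = 5, jitter = NA,
                         phase_jitter = NULL, sex = "female",
                         age_group = "under65") {
  s <- sample_subject(sex, age_group, effect_config(), rng_seed = seed)
  if (!is.null(phase_jitter)) s$phase_jitter_sd <- phase_jitter
  generate_walk(s, n_strides = n_strides,
                noise = noise_config(jitter_sd_px = jitter),
                rng_seed = seed + 5000)
}

# hand-built successful cycle segment (for degenerate-input tests)
manual_segment <- function(start, end, minima = NULL) {
  structure(list(status = "ok", reason = NA_character_,
                 minima_indices = minima %||% c(start, start, start, end, end),
                 cycle_index = 2L, start_frame = start, end_frame = end,
                 n_frames = end - start),
            class = "cycle_segment")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -----------------------------------------------------

# exhaustive interior strict-minimum scan with the same prominence rule,
# O(n^2), no smoothing
oracle_minima <- function(x, min_prominence_frac) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng == 0) return(integer())
  out <- integer()
  for (i in 2:(n - 1)) {
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) {
      v <- x[i]
      left <- x[seq_len(i - 1)]
      below_l <- which(left < v)
      lmax <- if (length(below_l)) max(left[(max(below_l) + 1):(i - 1)]) else max(left)
      right <- x[(i + 1):n]
      below_r <- which(right < v)
      rmax <- if (length(below_r)) max(right[seq_len(min(below_r) - 1)]) else max(right)
      if (min(lmax, rmax) - v >= min_prominence_frac * rng) out <- c(out, i - 1L)
    }
  }
  out
}

# two-pass central-moment oracle
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu, sd = sqrt(m2),
    skew = if (m2 == 0) 0 else m3 / m2^1.5,
    kurt = if (m2 == 0) 0 else m4 / m2^2 - 3)
}

# brute-force pairwise AUC with half credit for ties
oracle_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# a labelled feature tibble with one informative column and pure noise
toy_features <- function(n = 200, p_noise = 49, seed = 1, flip = 0.05) {
  withr::with_seed(seed, {
    y <- rep(c("a", "b"), length.out = n)
    informative <- ifelse(y == "b", 1, -1) + rnorm(n, 0, 0.5)
    noise <- matrix(rnorm(n * p_noise), n)
    colnames(noise) <- sprintf("noise%02d", seq_len(p_noise))
    dplyr::bind_cols(
      tibble::tibble(recording_id = sprintf("r%03d", seq_len(n)),
                     signal = informative, outcome = y),
      tibble::as_tibble(noise))
  })
}

# cohort where `flagged` recordings carry morphology drawn from the opposite
# sex to their recorded label (atypical individuals that should be predicted
# poorly); labels and walks otherwise standard
atypical_cohort <- function(n, flagged, seed) {
  rows <- lapply(seq_len(n), function(i) {
    sex_label <- if (i %% 3 == 0) "male" else "female"
    true_sex <- if (i %in% flagged) setdiff(c("male", "female"), sex_label) else sex_label
    ag <- if (i %% 5 == 0) "over65eq" else "under65"
    s <- sample_subject(true_sex, ag, effect_config(), rng_seed = seed * 1000 + i)
    w <- generate_walk(s, 5, noise = noise_config(), rng_seed = seed * 2000 + i)
    tibble::tibble(recording_id = sprintf("rec%04d", i), sex = sex_label,
                   age_years = if (ag == "over65eq") 70 else 40,
                   age_group = ag, bmi = 23, site = "india",
                   reference_length_m = 1, reference_length_px = 200,
                   pose = list(w))
  })
  dplyr::bind_rows(rows)
}
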