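# Gait-cycle detection from the ankle-to-ankle distance signal.
#
# A gait cycle is the span of three consecutive local minima of the distance
# between the left and right ankle landmarks (the two moments per stride
# when the feet pass each other). Exact zeros never occur in noisy pose
# estimates, so prominent local minima stand in for them. Only the *second*
# cycle is analysed downstream, so features are unaffected by edge effects
# at the start of a recording. Failures are values, not exceptions: the
# cohort-level feasibility proportion counts them.

#' Ankle-to-ankle distance signal
#'
#' Per-frame Euclidean distance between the left and right ankle landmarks,
#' in the units of the sequence's coordinate space.
#'
#' @param seq a [pose_sequence()].
#' @return A tibble of class `ankle_signal` with columns `frame`, `distance`
#'   and the frame rate as an attribute.
#' @export
ankle_distance <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  li <- landmark_index("left_ankle"); ri <- landmark_index("right_ankle")
  l <- seq[seq$landmark == li, ]
  r <- seq[seq$landmark == ri, ]
  out <- tibble::tibble(frame = l$frame,
                        distance = sqrt((l$x - r$x)^2 + (l$y - r$y)^2))
  structure(out, frame_rate_hz = frame_rate(seq),
            class = c("ankle_signal", class(tibble::tibble())))
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Topographic prominence of a local minimum at position i (1-based) of x:
# the drop from the lower of the two highest barriers reached before a
# strictly lower value (or the signal edge) on each side.
minimum_prominence <- function(x, i) {
  v <- x[i]
  n <- length(x)
  left_max <- -Inf
  j <- i - 1L
  while (j >= 1L && x[j] >= v) {
    if (x[j] > left_max) left_max <- x[j]
    j <- j - 1L
  }
  if (j < 1L && is.infinite(left_max)) left_max <- v
  right_max <- -Inf
  j <- i + 1L
  while (j <= n && x[j] >= v) {
    if (x[j] > right_max) right_max <- x[j]
    j <- j + 1L
  }
  if (j > n && is.infinite(right_max)) right_max <- v
  min(left_max, right_max) - v
}

#' Detect prominent local minima of a signal
#'
#' Smooths with a centred moving average, then finds strict interior local
#' minima (value lower than both neighbours; a flat plateau that is lower
#' than both its flanks counts once, at its leftmost frame) and keeps those
#' whose topographic prominence is at least `min_prominence_frac` of the
#' smoothed signal's range. A constant signal yields no minima.
#'
#' @param signal an [ankle_distance()] result, or a numeric vector.
#' @param smoothing_window odd moving-average window in frames (default 5).
#' @param min_prominence_frac minimum prominence as a fraction of the signal
#'   range (default 0.1).
#' @return Integer vector of frame indices (0-based, strictly increasing).
#' @export
detect_minima <- function(signal, smoothing_window = 5L,
                          min_prominence_frac = 0.1) {
  x <- if (inherits(signal, "ankle_signal")) signal$distance else as.numeric(signal)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L) {
    abort_gait("smoothing_window must be a positive odd integer", "gait_validation_error")
  }
  if (length(x) < smoothing_window) {
    abort_gait("signal shorter than the smoothing window", "gait_validation_error")
  }
  s <- moving_average(x, smoothing_window)
  n <- length(s)
  rng <- max(s) - min(s)
  if (rng == 0) return(integer())
  thresh <- min_prominence_frac * rng
  cand <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] < s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[i]) j <- j + 1L   # plateau scan
      if (j < n && s[j + 1L] > s[i]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  keep <- vapply(cand, function(i) minimum_prominence(s, i) >= thresh, logical(1))
  as.integer(cand[keep] - 1L)
}

#' Extract the second gait cycle
#'
#' With detected minima m1 < m2 < ... the non-overlapping cycle tiling
#' assigns cycle 1 to \[m1, m3), cycle 2 to \[m3, m5), and so on (half-open
#' frame windows sharing endpoints). At least five minima are required;
#' otherwise a typed failure is returned, not an exception. Sequences whose
#' inter-minima gaps are too irregular to be walking (coefficient of
#' variation above `max_gap_cv`) also fail: smoothed non-gait noise produces
#' many spurious minima, and the regularity guard is what rejects it.
#'
#' @param seq a [pose_sequence()].
#' @param smoothing_window,min_prominence_frac passed to [detect_minima()].
#' @param max_gap_cv maximum coefficient of variation of inter-minima gaps
#'   for a plausible gait rhythm (default 0.20).
#' @return A list of class `cycle_segment` with `status` (`"ok"` or
#'   `"failed"`), `reason` (`NA`, `"insufficient_minima"` or
#'   `"irregular_minima"`), `minima_indices`, `cycle_index` (always 2),
#'   `start_frame`, `end_frame` (half-open) and `n_frames`.
#' @export
extract_second_cycle <- function(seq, smoothing_window = 5L,
                                 min_prominence_frac = 0.1,
                                 max_gap_cv = 0.20) {
  sig <- ankle_distance(seq)
  minima <- if (length(sig$distance) >= smoothing_window) {
    detect_minima(sig, smoothing_window, min_prominence_frac)
  } else integer()
  fail <- function(reason) {
    structure(list(status = "failed", reason = reason,
                   minima_indices = minima, cycle_index = 2L,
                   start_frame = NA_integer_, end_frame = NA_integer_,
                   n_frames = NA_integer_),
              class = "cycle_segment")
  }
  if (length(minima) < 5L) return(fail("insufficient_minima"))
  gaps <- diff(minima)
  cv <- stats::sd(gaps) / mean(gaps)
  if (is.finite(cv) && cv > max_gap_cv) return(fail("irregular_minima"))
  start <- minima[3L]
  end <- minima[5L]
  structure(list(status = "ok", reason = NA_character_,
                 minima_indices = minima, cycle_index = 2L,
                 start_frame = start, end_frame = end,
                 n_frames = end - start),
            class = "cycle_segment")
}

#' @exportS3Method base::print
print.cycle_segment <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<cycle_segment> cycle 2: frames [%d, %d), %d frames, %d minima\n",
                x$start_frame, x$end_frame, x$n_frames, length(x$minima_indices)))
  } else {
    cat(sprintf("<cycle_segment> FAILED (%s), %d minima\n",
                x$reason, length(x$minima_indices)))
  }
  invisible(x)
}

#' Segment every recording of a cohort
#'
#' @param cohort a cohort tibble with `recording_id` and a `pose`
#'   list-column (see [sample_cohort()]).
#' @param ... passed to [extract_second_cycle()].
#' @return A tibble with one row per recording: `recording_id`, `status`,
#'   `reason`, `start_frame`, `end_frame`, `n_frames`, `n_minima`, and a
#'   `segment` list-column.
#' @export
segment_cohort <- function(cohort, ...) {
  segs <- purrr::map(cohort$pose, extract_second_cycle, ...)
  tibble::tibble(
    recording_id = cohort$recording_id,
    status = purrr::map_chr(segs, "status"),
    reason = purrr::map_chr(segs, "reason"),
    start_frame = purrr::map_int(segs, ~ as.integer(.x$start_frame)),
    end_frame = purrr::map_int(segs, ~ as.integer(.x$end_frame)),
    n_frames = purrr::map_int(segs, ~ as.integer(.x$n_frames)),
    n_minima = purrr::map_int(segs, ~ length(.x$minima_indices)),
    segment = segs
  )
}

#' Extraction feasibility of a cohort
#'
#' The proportion of recordings for which a second gait cycle could be
#' extracted — the pipeline's feasibility metric.
#'
#' @param segments output of [segment_cohort()], or a list of
#'   `cycle_segment` objects.
#' @return A one-row tibble: `n_success`, `n_total`, `proportion`.
#' @export
feasibility <- function(segments) {
  status <- if (is.data.frame(segments)) {
    segments$status
  } else {
    vapply(segments, function(s) s$status, character(1))
  }
  if (length(status) < 1L) abort_gait("no recordings", "gait_validation_error")
  n_ok <- sum(status == "ok")
  tibble::tibble(n_success = n_ok, n_total = length(status),
                 proportion = n_ok / length(status))
}
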