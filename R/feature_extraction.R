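# The 109-feature geometric vector: 15 joint-pair distances and 12 joint
# angles per frame over the second gait cycle, each summarised by four
# moments (mean, SD, skewness, excess kurtosis), plus the cycle frame count
# as a walking-speed surrogate. 15*4 + 12*4 + 1 = 109.
#
# The default pair and triplet sets are a documented reconstruction of the
# usual full-body geometric feature recipe (trunk box, limb segments, foot
# segments; interior angles at the major joints): they are config-replaceable
# and validated against the landmark name enum at load.

#' Default joint-pair set for distance features
#'
#' Fifteen landmark pairs: trunk box edges, upper- and lower-limb segments,
#' the ankle-to-ankle span and both foot segments. Replaceable by any
#' 15-pair table with columns `a`, `b` of landmark names.
#'
#' @return A 15-row tibble with columns `a`, `b`, `base` (feature base name).
#' @export
default_distance_pairs <- function() {
  p <- tibble::tribble(
    ~a, ~b,
    "left_shoulder", "right_shoulder",
    "left_hip", "right_hip",
    "left_shoulder", "left_hip",
    "right_shoulder", "right_hip",
    "left_elbow", "left_shoulder",
    "right_elbow", "right_shoulder",
    "left_wrist", "left_elbow",
    "right_wrist", "right_elbow",
    "left_knee", "left_hip",
    "right_knee", "right_hip",
    "left_ankle", "left_knee",
    "right_ankle", "right_knee",
    "left_ankle", "right_ankle",
    "left_heel", "left_foot_index",
    "right_heel", "right_foot_index")
  p$base <- paste0("d_", p$a, "_", p$b)
  validate_pair_set(p)
}

#' Default joint-angle triplet set
#'
#' Twelve interior angles: elbows, shoulders, hips, knees, ankles (left and
#' right), plus trunk inclination (nose - mid-shoulder - mid-hip) and a neck
#' angle (left ear - nose - mid-shoulder). `mid_shoulder` and `mid_hip` are
#' virtual midpoints computed on the fly, not landmarks. The feature is the
#' interior angle at `vertex` between rays vertex->a and vertex->b, radians.
#'
#' @return A 12-row tibble with columns `name`, `a`, `vertex`, `b`.
#' @export
default_angle_triplets <- function() {
  t <- tibble::tribble(
    ~name, ~a, ~vertex, ~b,
    "left_elbow",  "left_shoulder",  "left_elbow",  "left_wrist",
    "right_elbow", "right_shoulder", "right_elbow", "right_wrist",
    "left_shoulder",  "left_hip",  "left_shoulder",  "left_elbow",
    "right_shoulder", "right_hip", "right_shoulder", "right_elbow",
    "left_hip",  "left_shoulder",  "left_hip",  "left_knee",
    "right_hip", "right_shoulder", "right_hip", "right_knee",
    "left_knee",  "left_hip",  "left_knee",  "left_ankle",
    "right_knee", "right_hip", "right_knee", "right_ankle",
    "left_ankle",  "left_knee",  "left_ankle",  "left_foot_index",
    "right_ankle", "right_knee", "right_ankle", "right_foot_index",
    "trunk", "nose", "mid_shoulder", "mid_hip",
    "neck", "left_ear", "nose", "mid_shoulder")
  validate_triplet_set(t)
}

#' @rdname default_distance_pairs
#' @param pairs a candidate pair table.
#' @export
validate_pair_set <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) != 15L) {
    abort_gait("distance pair set must contain exactly 15 pairs", "gait_config_error")
  }
  landmark_index(pairs$a); landmark_index(pairs$b)
  key <- purrr::map2_chr(pairs$a, pairs$b, ~ paste(sort(c(.x, .y)), collapse = "|"))
  if (anyDuplicated(key)) {
    abort_gait("duplicate unordered pair in distance pair set", "gait_config_error")
  }
  if (!"base" %in% names(pairs)) pairs$base <- paste0("d_", pairs$a, "_", pairs$b)
  pairs
}

#' @rdname default_angle_triplets
#' @param triplets a candidate triplet table.
#' @export
validate_triplet_set <- function(triplets) {
  triplets <- tibble::as_tibble(triplets)
  if (nrow(triplets) != 12L) {
    abort_gait("angle triplet set must contain exactly 12 triplets", "gait_config_error")
  }
  ok_names <- c(landmark_names(), virtual_point_names())
  for (col in c("a", "vertex", "b")) {
    bad <- setdiff(triplets[[col]], ok_names)
    if (length(bad)) {
      abort_gait(sprintf("unknown point name(s) in triplet set: %s",
                         paste(bad, collapse = ", ")), "gait_config_error")
    }
  }
  if (any(triplets$a == triplets$vertex | triplets$b == triplets$vertex)) {
    abort_gait("triplet endpoints must differ from the vertex", "gait_config_error")
  }
  triplets
}

#' Pixel-to-meter scale from the in-video reference object
#'
#' @param reference_length_m known physical length of the reference object
#'   (e.g. a 1 m measuring tape), meters.
#' @param reference_length_px its apparent length in the image, pixels.
#' @return `meters_per_pixel` as a numeric scalar.
#' @export
pixel_scale <- function(reference_length_m, reference_length_px) {
  assert_scalar_num(reference_length_m, "reference_length_m", positive = TRUE)
  assert_scalar_num(reference_length_px, "reference_length_px", positive = TRUE)
  reference_length_m / reference_length_px
}

# point coordinates (n_frames x 2) for a landmark or virtual midpoint name,
# from x/y frame-by-landmark matrices
point_coords <- function(name, xs, ys) {
  if (name == "mid_shoulder") {
    i <- landmark_index(c("left_shoulder", "right_shoulder")) + 1L
    cbind(rowMeans(xs[, i, drop = FALSE]), rowMeans(ys[, i, drop = FALSE]))
  } else if (name == "mid_hip") {
    i <- landmark_index(c("left_hip", "right_hip")) + 1L
    cbind(rowMeans(xs[, i, drop = FALSE]), rowMeans(ys[, i, drop = FALSE]))
  } else {
    i <- landmark_index(name) + 1L
    cbind(xs[, i], ys[, i])
  }
}

#' Per-frame joint-pair distances
#'
#' Euclidean distances between each configured landmark pair, converted to
#' meters by the reference-object scale.
#'
#' @param seq a pixel-space [pose_sequence()] (or any subset of its frames).
#' @param pairs a pair table (see [default_distance_pairs()]).
#' @param meters_per_pixel scale from [pixel_scale()].
#' @return A tibble with columns `frame`, one column per pair base name,
#'   values in meters.
#' @export
frame_distances <- function(seq, pairs = default_distance_pairs(),
                            meters_per_pixel = 1) {
  pairs <- validate_pair_set(pairs)
  assert_scalar_num(meters_per_pixel, "meters_per_pixel", positive = TRUE)
  xs <- coord_matrix(seq, "x"); ys <- coord_matrix(seq, "y")
  out <- purrr::map2(pairs$a, pairs$b, function(a, b) {
    pa <- point_coords(a, xs, ys); pb <- point_coords(b, xs, ys)
    sqrt((pa[, 1] - pb[, 1])^2 + (pa[, 2] - pb[, 2])^2) * meters_per_pixel
  })
  names(out) <- pairs$base
  dplyr::bind_cols(tibble::tibble(frame = unique(seq$frame)), tibble::as_tibble(out))
}

#' Per-frame joint angles
#'
#' Interior angle at each triplet's vertex between the rays vertex->a and
#' vertex->b: the arc-cosine of the clamped cosine, in \[0, pi\] radians.
#' Angles are invariant under translation, rotation and uniform scaling of
#' the frame. A zero-length ray makes the angle undefined; it is encoded as
#' 0 and the affected frames are flagged in the `degenerate` attribute.
#'
#' @param seq a [pose_sequence()] (any coordinate space; angles are
#'   scale-free).
#' @param triplets a triplet table (see [default_angle_triplets()]).
#' @return A tibble with columns `frame` and one column per angle name
#'   (prefixed `ang_`), radians.
#' @export
frame_angles <- function(seq, triplets = default_angle_triplets()) {
  triplets <- validate_triplet_set(triplets)
  xs <- coord_matrix(seq, "x"); ys <- coord_matrix(seq, "y")
  degenerate <- character()
  out <- purrr::pmap(list(triplets$a, triplets$vertex, triplets$b, triplets$name),
                     function(a, v, b, nm) {
    pa <- point_coords(a, xs, ys); pv <- point_coords(v, xs, ys)
    pb <- point_coords(b, xs, ys)
    u <- pa - pv; w <- pb - pv
    nu <- sqrt(rowSums(u^2)); nw <- sqrt(rowSums(w^2))
    bad <- nu == 0 | nw == 0
    cosang <- rep(1, length(nu))
    ok <- !bad
    cosang[ok] <- pmin(1, pmax(-1, (u[ok, 1] * w[ok, 1] + u[ok, 2] * w[ok, 2]) /
                                 (nu[ok] * nw[ok])))
    ang <- acos(cosang)
    ang[bad] <- 0
    if (any(bad)) degenerate <<- c(degenerate, nm)
    ang
  })
  names(out) <- paste0("ang_", triplets$name)
  res <- dplyr::bind_cols(tibble::tibble(frame = unique(seq$frame)),
                          tibble::as_tibble(out))
  attr(res, "degenerate") <- degenerate
  res
}

#' Four-moment summary of a per-frame series
#'
#' Population (n-denominator) moments: mean; SD = sqrt(m2); skewness
#' g1 = m3 / m2^(3/2); excess kurtosis g2 = m4 / m2^2 - 3, with central
#' moments m_k computed with denominator n. A constant series (m2 = 0) gets
#' skewness and kurtosis 0 (flagged, not NaN) so downstream matrices stay
#' dense.
#'
#' @param series numeric vector, length >= 1.
#' @return A named list: `mean`, `sd`, `skew`, `kurt`, `degenerate`.
#' @export
moment_summary <- function(series) {
  if (length(series) < 1L) abort_gait("series must be nonempty", "gait_validation_error")
  n <- length(series)
  mu <- mean(series)
  d <- series - mu
  m2 <- mean(d^2)
  if (m2 == 0) {
    return(list(mean = mu, sd = 0, skew = 0, kurt = 0, degenerate = TRUE))
  }
  m3 <- mean(d^3); m4 <- mean(d^4)
  list(mean = mu, sd = sqrt(m2), skew = m3 / m2^1.5, kurt = m4 / m2^2 - 3,
       degenerate = FALSE)
}

#' Extract the 109-feature vector for one recording
#'
#' Computes the 15 distance and 12 angle series over the second-cycle frame
#' window \[start_frame, end_frame), summarises each by its four moments, and
#' appends the cycle frame count (`cycle_n_frames`) as the walking-speed
#' surrogate. Feature names follow `{base}_{stat}` with
#' `stat` in mean/sd/skew/kurt; ordering is frozen (distances in pair order,
#' then angles in triplet order, then the surrogate).
#'
#' @param seq a pixel-space [pose_sequence()].
#' @param segment a successful `cycle_segment` from [extract_second_cycle()].
#' @param meters_per_pixel reference-object scale (see [pixel_scale()]).
#' @param pairs,triplets feature definitions; defaults are the standard sets.
#' @return A one-row tibble with 109 feature columns. Degenerate
#'   (zero-variance or zero-ray) bases are listed in the
#'   `degenerate_features` attribute.
#' @export
extract_features <- function(seq, segment,
                             meters_per_pixel = 1,
                             pairs = default_distance_pairs(),
                             triplets = default_angle_triplets()) {
  stopifnot(inherits(segment, "cycle_segment"))
  if (segment$status != "ok") {
    abort_gait(sprintf("cannot extract features from a failed segment (%s); filter feasibility failures first",
                       segment$reason), "gait_segment_error")
  }
  if (coordinate_space(seq) != "pixel") {
    abort_gait("sequence must be in pixel space (see to_pixel_space())", "gait_config_error")
  }
  win <- seq[seq$frame >= segment$start_frame & seq$frame < segment$end_frame, ]
  attrs <- attributes(seq)
  for (a in c("frame_rate_hz", "coordinate_space", "image_width_px", "image_height_px")) {
    attr(win, a) <- attrs[[a]]
  }
  class(win) <- class(seq)
  dists <- frame_distances(win, pairs, meters_per_pixel)
  angs <- frame_angles(win, triplets)
  series <- c(as.list(dists[-1L]), as.list(angs[-1L]))
  degenerate <- attr(angs, "degenerate")
  vals <- list()
  for (nm in names(series)) {
    ms <- moment_summary(series[[nm]])
    vals[[paste0(nm, "_mean")]] <- ms$mean
    vals[[paste0(nm, "_sd")]] <- ms$sd
    vals[[paste0(nm, "_skew")]] <- ms$skew
    vals[[paste0(nm, "_kurt")]] <- ms$kurt
    if (ms$degenerate) degenerate <- unique(c(degenerate, nm))
  }
  vals$cycle_n_frames <- as.double(segment$n_frames)
  out <- tibble::as_tibble(vals)
  stopifnot(ncol(out) == 109L)
  attr(out, "degenerate_features") <- degenerate
  out
}

#' Feature names in frozen order
#' @param pairs,triplets feature definitions.
#' @return Character vector of the 109 feature names.
#' @export
feature_names <- function(pairs = default_distance_pairs(),
                          triplets = default_angle_triplets()) {
  bases <- c(validate_pair_set(pairs)$base,
             paste0("ang_", validate_triplet_set(triplets)$name))
  c(as.vector(t(outer(bases, c("mean", "sd", "skew", "kurt"), paste, sep = "_"))),
    "cycle_n_frames")
}

#' Extract the labelled feature table for a cohort
#'
#' Segments every recording (unless segments are supplied), drops
#' feasibility failures, and returns one feature row per successful
#' recording joined with its labels and covariates. The feasibility summary
#' is attached as the `feasibility` attribute.
#'
#' @param cohort a cohort tibble (see [sample_cohort()]); must carry
#'   `recording_id`, `pose`, `reference_length_m`, `reference_length_px`
#'   and label columns.
#' @param segments optional [segment_cohort()] output.
#' @param pairs,triplets feature definitions.
#' @param ... passed to [segment_cohort()] when segments are computed here.
#' @return A tibble: `recording_id`, 109 feature columns, then label /
#'   covariate columns present in the cohort (`sex`, `age_group`, `bmi`,
#'   `site`, ...).
#' @export
extract_cohort_features <- function(cohort, segments = NULL,
                                    pairs = default_distance_pairs(),
                                    triplets = default_angle_triplets(), ...) {
  if (is.null(segments)) segments <- segment_cohort(cohort, ...)
  feas <- feasibility(segments)
  ok <- which(segments$status == "ok")
  rows <- purrr::map(ok, function(i) {
    mpp <- pixel_scale(cohort$reference_length_m[i], cohort$reference_length_px[i])
    fv <- extract_features(cohort$pose[[i]], segments$segment[[i]],
                           meters_per_pixel = mpp, pairs = pairs,
                           triplets = triplets)
    dplyr::bind_cols(tibble::tibble(recording_id = cohort$recording_id[i]), fv)
  })
  out <- dplyr::bind_rows(rows)
  label_cols <- intersect(c("sex", "age_years", "age_group", "bmi", "site"),
                          names(cohort))
  out <- dplyr::left_join(out,
                          dplyr::select(cohort, "recording_id",
                                        dplyr::all_of(label_cols)),
                          by = "recording_id")
  attr(out, "feasibility") <- feas
  out
}
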