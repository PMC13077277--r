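# Pose-landmark sequence container and I/O.
#
# A pose sequence is stored long: one row per landmark per frame, which keeps
# the object pipe-friendly (it *is* a tibble) while carrying acquisition
# metadata (frame rate, coordinate space, image size) as attributes.

#' Construct a pose sequence
#'
#' Builds a validated pose-landmark sequence from a long data frame with one
#' row per landmark per frame. Every frame must contain exactly 33 landmarks
#' (indices 0-32, see [landmark_names()]); frames are ordered by frame index.
#' In normalized coordinate space, x and y are clipped to \[0, 1\] with a
#' warning if any value falls outside.
#'
#' @param data data frame with columns `frame`, `landmark`, `x`, `y` and
#'   optionally `visibility` (defaults to 1 when absent or missing).
#' @param frame_rate_hz frames per second (default 30, the smartphone
#'   recording rate the pipeline assumes).
#' @param coordinate_space `"pixel"` or `"normalized"`.
#' @param image_width_px,image_height_px image dimensions in pixels; required
#'   to convert a normalized-space sequence to pixel space.
#' @return A tibble of class `pose_sequence` with columns
#'   `frame`, `landmark`, `x`, `y`, `visibility`.
#' @export
pose_sequence <- function(data, frame_rate_hz = 30,
                          coordinate_space = c("pixel", "normalized"),
                          image_width_px = NULL, image_height_px = NULL) {
  coordinate_space <- match.arg(coordinate_space)
  assert_scalar_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  data <- tibble::as_tibble(data)
  required <- c("frame", "landmark", "x", "y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort_gait(sprintf("pose data lacks column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "gait_schema_error")
  }
  if (!"visibility" %in% names(data)) data$visibility <- 1
  data$visibility[is.na(data$visibility)] <- 1
  if (nrow(data) == 0L) {
    abort_gait("pose sequence must contain at least one frame", "gait_validation_error")
  }
  data <- dplyr::arrange(data, .data$frame, .data$landmark)
  per_frame <- table(data$frame)
  if (any(per_frame != 33L) ||
      !all(vapply(split(data$landmark, data$frame),
                  function(l) identical(as.integer(l), 0:32), logical(1)))) {
    bad <- names(per_frame)[per_frame != 33L]
    abort_gait(sprintf("every frame must carry exactly the 33 landmarks 0-32 (offending frame(s): %s)",
                       paste(utils::head(bad, 3), collapse = ", ")),
               "gait_schema_error")
  }
  if (any(!is.finite(data$x)) || any(!is.finite(data$y))) {
    abort_gait("non-finite landmark coordinates", "gait_validation_error")
  }
  if (any(data$visibility < 0 | data$visibility > 1)) {
    abort_gait("visibility must lie in [0, 1]", "gait_validation_error")
  }
  if (coordinate_space == "normalized") {
    out_of_range <- data$x < 0 | data$x > 1 | data$y < 0 | data$y > 1
    if (any(out_of_range)) {
      rlang::warn(sprintf("%d normalized coordinates outside [0, 1] were clipped",
                          sum(out_of_range)))
      data$x <- pmin(pmax(data$x, 0), 1)
      data$y <- pmin(pmax(data$y, 0), 1)
    }
  }
  if (!is.null(image_width_px)) assert_scalar_num(image_width_px, "image_width_px", positive = TRUE)
  if (!is.null(image_height_px)) assert_scalar_num(image_height_px, "image_height_px", positive = TRUE)
  data$frame <- as.integer(data$frame)
  data$landmark <- as.integer(data$landmark)
  structure(data,
            frame_rate_hz = as.double(frame_rate_hz),
            coordinate_space = coordinate_space,
            image_width_px = if (is.null(image_width_px)) NULL else as.double(image_width_px),
            image_height_px = if (is.null(image_height_px)) NULL else as.double(image_height_px),
            class = c("pose_sequence", class(tibble::tibble())))
}

#' @exportS3Method base::print
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames x 33 landmarks, %g Hz, %s space\n",
              n_frames(x), frame_rate(x), coordinate_space(x)))
  NextMethod()
}

#' Number of frames in a pose sequence
#' @param seq a `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(unique(seq$frame))

#' @rdname n_frames
#' @export
frame_rate <- function(seq) attr(seq, "frame_rate_hz")

#' @rdname n_frames
#' @export
coordinate_space <- function(seq) attr(seq, "coordinate_space")

# frames x 33 matrix of one coordinate, for fast vectorised geometry
coord_matrix <- function(seq, which = c("x", "y")) {
  which <- match.arg(which)
  matrix(seq[[which]], ncol = 33L, byrow = TRUE)
}

#' Convert a pose sequence to pixel space
#'
#' Normalized coordinates are rescaled by the stored image dimensions
#' (`x' = x * width`, `y' = y * height`); a pixel-space input is returned
#' unchanged, so the operation is idempotent.
#'
#' @param seq a `pose_sequence`.
#' @return A pixel-space `pose_sequence`.
#' @export
to_pixel_space <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (coordinate_space(seq) == "pixel") return(seq)
  w <- attr(seq, "image_width_px"); h <- attr(seq, "image_height_px")
  if (is.null(w) || is.null(h)) {
    abort_gait("normalized pose sequence lacks image dimensions; cannot convert to pixel space",
               "gait_config_error")
  }
  out <- seq
  out$x <- seq$x * w
  out$y <- seq$y * h
  attr(out, "coordinate_space") <- "pixel"
  out
}

fmt_coord <- function(x) trimws(formatC(x, digits = 17, format = "g"))

#' Read and write pose sequences
#'
#' Two plain-text schemas are supported. `csv_long`: header
#' `frame,landmark,x,y,visibility`, one row per landmark per frame.
#' `jsonl_frames`: one JSON object per line,
#' `{"frame": int, "landmarks": [[x, y, vis] x 33]}`. Writing is bit-stable:
#' identical sequences produce byte-identical files (fixed column order and
#' full-precision float formatting), and a read of a written file reproduces
#' the sequence exactly.
#'
#' @param path file path.
#' @param schema `"csv_long"` or `"jsonl_frames"`.
#' @param frame_rate_hz,coordinate_space,image_width_px,image_height_px
#'   sequence metadata (not stored in the file formats themselves).
#' @return `read_pose_sequence()` returns a `pose_sequence`;
#'   `write_pose_sequence()` returns `path` invisibly.
#' @export
read_pose_sequence <- function(path, schema = c("csv_long", "jsonl_frames"),
                               frame_rate_hz = 30,
                               coordinate_space = "pixel",
                               image_width_px = NULL, image_height_px = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort_gait(sprintf("pose file not found: %s", path), "gait_io_error")
  }
  if (schema == "csv_long") {
    df <- tryCatch(
      utils::read.csv(path, colClasses = c("integer", "integer", "numeric",
                                           "numeric", "numeric")),
      error = function(e) abort_gait(sprintf("malformed csv_long pose file %s: %s",
                                             path, conditionMessage(e)),
                                     "gait_parse_error"))
    expected <- c("frame", "landmark", "x", "y", "visibility")
    if (!identical(names(df), expected)) {
      abort_gait(sprintf("csv_long header must be %s", paste(expected, collapse = ",")),
                 "gait_parse_error")
    }
  } else {
    lines <- readLines(path)
    rows <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) abort_gait(
                        sprintf("malformed JSON at line %d of %s", i, path),
                        "gait_parse_error"))
      lm <- obj$landmarks
      if (is.null(dim(lm)) || nrow(lm) != 33L || ncol(lm) != 3L) {
        abort_gait(sprintf("line %d of %s: frame must carry a 33 x 3 landmark array",
                           i, path), "gait_schema_error")
      }
      tibble::tibble(frame = as.integer(obj$frame), landmark = 0:32,
                     x = lm[, 1], y = lm[, 2], visibility = lm[, 3])
    })
    df <- dplyr::bind_rows(rows)
  }
  pose_sequence(df, frame_rate_hz = frame_rate_hz,
                coordinate_space = coordinate_space,
                image_width_px = image_width_px,
                image_height_px = image_height_px)
}

#' @rdname read_pose_sequence
#' @param seq a `pose_sequence` to write.
#' @export
write_pose_sequence <- function(seq, path, schema = c("csv_long", "jsonl_frames")) {
  stopifnot(inherits(seq, "pose_sequence"))
  schema <- match.arg(schema)
  con <- tryCatch(file(path, "wb"), error = function(e)
    abort_gait(sprintf("cannot open %s for writing", path), "gait_io_error"))
  on.exit(close(con))
  if (schema == "csv_long") {
    lines <- c("frame,landmark,x,y,visibility",
               paste(seq$frame, seq$landmark, fmt_coord(seq$x), fmt_coord(seq$y),
                     fmt_coord(seq$visibility), sep = ","))
  } else {
    by_frame <- split(seq, seq$frame)
    lines <- vapply(by_frame, function(fr) {
      trip <- paste0("[", fmt_coord(fr$x), ",", fmt_coord(fr$y), ",",
                     fmt_coord(fr$visibility), "]")
      sprintf('{"frame":%d,"landmarks":[%s]}', fr$frame[1], paste(trip, collapse = ","))
    }, character(1))
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read recording metadata
#'
#' Parses the per-recording metadata table: one row per recording with sex,
#' age, BMI, study site, and the in-video reference-object lengths used to
#' convert pixel distances to meters. The binary age group (`under65` vs
#' `over65eq`) is derived as `age_years >= 65`.
#'
#' @param path CSV with header
#'   `recording_id,sex,age_years,bmi,site,reference_length_m,reference_length_px`.
#' @return A tibble with the input columns plus `age_group`.
#' @export
read_recording_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_recording_meta(tibble::as_tibble(df))
}

#' @rdname read_recording_meta
#' @param meta a metadata data frame to validate.
#' @export
validate_recording_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  required <- c("recording_id", "sex", "age_years", "bmi", "site",
                "reference_length_m", "reference_length_px")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort_gait(sprintf("metadata lacks column(s): %s", paste(missing_cols, collapse = ", ")),
               "gait_schema_error")
  }
  if (!all(meta$sex %in% c("male", "female"))) {
    abort_gait("sex must be 'male' or 'female'", "gait_validation_error")
  }
  if (!all(meta$site %in% c("thailand", "india"))) {
    abort_gait("site must be 'thailand' or 'india'", "gait_validation_error")
  }
  if (any(meta$age_years < 0) || any(meta$bmi <= 0) ||
      any(meta$reference_length_m <= 0) || any(meta$reference_length_px <= 0)) {
    abort_gait("age must be >= 0; bmi and reference lengths must be > 0",
               "gait_validation_error")
  }
  derived <- ifelse(meta$age_years >= 65, "over65eq", "under65")
  if ("age_group" %in% names(meta) && !all(meta$age_group == derived)) {
    abort_gait("age_group inconsistent with age_years (>= 65 rule)", "gait_validation_error")
  }
  meta$age_group <- derived
  meta
}
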