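# The 33-landmark identity map used by full-body 2D pose estimators.
# Indices are 0-based internally; downstream feature definitions always refer
# to landmarks by name, never by raw index, to eliminate off-by-one drift.

#' Pose landmark names
#'
#' The 33 named body landmarks emitted by full-body 2D pose estimation
#' (nose, eyes, ears, mouth corners, shoulders, elbows, wrists, hand points,
#' hips, knees, ankles, heels, foot indices), in canonical order. The
#' internal index of a landmark is its position in this vector minus one
#' (0-based, 0 to 32).
#'
#' @return Character vector of length 33.
#' @examples
#' landmark_names()[1]           # "nose"
#' match("left_ankle", landmark_names()) - 1L  # index 27
#' @export
landmark_names <- function() {
  c("nose",
    "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear",
    "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_pinky", "right_pinky",
    "left_index", "right_index",
    "left_thumb", "right_thumb",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_heel", "right_heel",
    "left_foot_index", "right_foot_index")
}

#' @keywords internal
landmark_index <- function(name) {
  idx <- match(name, landmark_names())
  if (anyNA(idx)) {
    abort_gait(sprintf("unknown landmark name(s): %s",
                       paste(name[is.na(idx)], collapse = ", ")),
               "gait_validation_error")
  }
  idx - 1L
}

# Virtual midpoints usable in angle-triplet definitions; computed on the fly,
# never counted as landmarks.
virtual_point_names <- function() c("mid_shoulder", "mid_hip")
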