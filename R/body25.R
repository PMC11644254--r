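#' BODY_25 keypoint table
#'
#' OpenPose's BODY_25 skeleton topology assigns each anatomical landmark a
#' fixed slot in the 75-float `pose_keypoints_2d` array. `BODY25` maps the
#' landmark names used throughout this package to those 0-based slots.
#'
#' The classifier consumes NOSE, NECK, MID_HIP, R_HIP and L_HIP; the
#' remaining slots are carried so that real OpenPose output loads unchanged
#' and the simulator can emit complete skeletons.
#'
#' @format Named integer vector of length 25; values are the 0-based
#'   BODY_25 indices, names are the landmark identifiers.
#' @examples
#' BODY25[["NOSE"]]     # 0
#' BODY25[["MID_HIP"]]  # 8
#' @export
BODY25 <- c(
  NOSE = 0L, NECK = 1L,
  R_SHOULDER = 2L, R_ELBOW = 3L, R_WRIST = 4L,
  L_SHOULDER = 5L, L_ELBOW = 6L, L_WRIST = 7L,
  MID_HIP = 8L,
  R_HIP = 9L, R_KNEE = 10L, R_ANKLE = 11L,
  L_HIP = 12L, L_KNEE = 13L, L_ANKLE = 14L,
  R_EYE = 15L, L_EYE = 16L, R_EAR = 17L, L_EAR = 18L,
  L_BIG_TOE = 19L, L_SMALL_TOE = 20L, L_HEEL = 21L,
  R_BIG_TOE = 22L, R_SMALL_TOE = 23L, R_HEEL = 24L
)

# 1-based matrix row for a named BODY_25 slot
kp_row <- function(name) BODY25[[name]] + 1L

#' Posture labels
#'
#' The six per-frame posture labels: `NORMAL`, the four camera-frame fall
#' directions, and `UNKNOWN` (no usable skeleton evidence). Left/right are
#' image directions: a subject whose trunk tips toward the left edge of the
#' image is a leftward fall.
#'
#' @format Character vector of length 6, in canonical level order.
#' @export
POSTURE_LEVELS <- c("NORMAL", "FALL_LEFT", "FALL_RIGHT", "FALL_BACK",
                    "FALL_FORWARD", "UNKNOWN")

#' @rdname POSTURE_LEVELS
#' @format `FALL_DIRECTIONS` is the subset of the four fall labels.
#' @export
FALL_DIRECTIONS <- POSTURE_LEVELS[2:5]

#' Human-readable posture names
#'
#' Maps the programmatic posture labels to the display strings used in
#' reports ("Leftward Fall", "Rightward Fall", ...).
#'
#' @param labels character vector or factor of posture labels.
#' @return Character vector of display names.
#' @export
posture_display <- function(labels) {
  map <- c(NORMAL = "Normal", FALL_LEFT = "Leftward Fall",
           FALL_RIGHT = "Rightward Fall", FALL_BACK = "Backward Fall",
           FALL_FORWARD = "Forward Fall", UNKNOWN = "unknown")
  unname(map[as.character(labels)])
}

as_posture_factor <- function(x) factor(as.character(x), levels = POSTURE_LEVELS)
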