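#' Angle between a keypoint segment and the image vertical axis
#'
#' The core posture feature: the signed angle, in degrees, between the
#' segment from `a` to `b` and the vertical axis of the image, computed as
#' `degrees(atan2(a_h - b_h, a_w - b_w) - pi/2)` and wrapped to the interval
#' (-180, 180] (a raw value of exactly -180 maps to +180).
#'
#' With image coordinates (y grows downward) the convention is: 0 when `a`
#' is directly below `b` (segment upright, `b` above), positive when `b`
#' leans to the image right of `a` (for magnitudes below 90), and +/-90 for
#' a horizontal segment.
#'
#' @param a,b numeric length-2 vectors `c(x, y)` in image coordinates.
#' @return Angle in degrees, in (-180, 180].
#' @examples
#' segment_vertical_angle(c(100, 150), c(100, 50))  #   0: a below b
#' segment_vertical_angle(c(150, 100), c(50, 100))  # -90: horizontal
#' @export
segment_vertical_angle <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, is.finite(a), is.finite(b))
  if (a[1] == b[1] && a[2] == b[2])
    stop("degenerate geometry: coincident points have no direction")
  unname(wrap_angle_deg((atan2(a[2] - b[2], a[1] - b[1]) - pi / 2) *
                          180 / pi))
}

# wrap degrees into (-180, 180]; exactly -180 becomes +180
wrap_angle_deg <- function(d) {
  d <- d %% 360
  ifelse(d > 180, d - 360, d)
}

#' Vertical height difference between two keypoints
#'
#' `a_h - b_h` in pixels: positive when `a` sits below `b` on screen
#' (image y grows downward). For the trunk feature the arguments are
#' (MID_HIP, NECK), so a standing subject gives a large positive value and a
#' collapsed or inverted trunk drives it toward zero or negative.
#'
#' @param a,b numeric length-2 vectors `c(x, y)` in image coordinates.
#' @return Height difference in pixels.
#' @export
height_difference <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2)
  unname(a[2] - b[2])
}

#' Estimate the subject's body scale in pixels
#'
#' Distance invariance: the same person fills different pixel heights at
#' different camera distances, so all classifier thresholds are expressed as
#' ratios to a per-subject pixel scale. The scale is the median trunk length
#' `|MID_HIP - NECK|` over the frames of `window` where both endpoints are
#' valid (MID_HIP may be substituted by the hip midpoint); if no frame
#' qualifies it falls back to twice the median hip width `|L_HIP - R_HIP|`,
#' and as a last resort to `config$default_scale`. Always positive.
#'
#' @param window a [pose_sequence] (typically the leading calibration
#'   frames of a sequence).
#' @param config a [classifier_config] (supplies `min_confidence` and
#'   `default_scale`).
#' @return Body scale in pixels (> 0).
#' @export
body_scale <- function(window, config = classifier_config()) {
  stopifnot(inherits(window, "pose_sequence"), n_frames(window) > 0)
  trunk <- numeric(0)
  hipw <- numeric(0)
  for (i in seq_len(n_frames(window))) {
    kp <- frame_keypoints(window, i)
    ok <- kp[, 3] >= config$min_confidence
    mh <- effective_mid_hip(kp, ok)
    if (!is.null(mh) && ok[kp_row("NECK")]) {
      len <- sqrt(sum((mh - kp[kp_row("NECK"), 1:2])^2))
      if (len > 0) trunk <- c(trunk, len)
    }
    if (ok[kp_row("L_HIP")] && ok[kp_row("R_HIP")]) {
      w <- sqrt(sum((kp[kp_row("L_HIP"), 1:2] - kp[kp_row("R_HIP"), 1:2])^2))
      if (w > 0) hipw <- c(hipw, w)
    }
  }
  if (length(trunk)) return(stats::median(trunk))
  if (length(hipw)) return(2 * stats::median(hipw))
  config$default_scale
}

# MID_HIP coordinates, substituting the L/R hip midpoint when MID_HIP itself
# is missing (it is a derived joint in the BODY_25 topology). NULL if neither
# route is available.
effective_mid_hip <- function(kp, ok) {
  if (ok[kp_row("MID_HIP")]) return(kp[kp_row("MID_HIP"), 1:2])
  if (ok[kp_row("L_HIP")] && ok[kp_row("R_HIP")])
    return((kp[kp_row("L_HIP"), 1:2] + kp[kp_row("R_HIP"), 1:2]) / 2)
  NULL
}

#' Geometric posture features for one frame
#'
#' Computes the per-frame quantities the fall rules consume:
#' \describe{
#'   \item{trunk_angle}{MID_HIP -> NECK segment vs vertical, degrees.}
#'   \item{head_angle}{NECK -> NOSE segment vs vertical, degrees.}
#'   \item{hip_line_angle}{L_HIP -> R_HIP segment vs vertical, degrees
#'     (+/-90 when the subject stands square to the camera). Exported for
#'     experimentation; unused by the default rule cascade.}
#'   \item{trunk_hd}{`MID_HIP_y - NECK_y`, pixels.}
#'   \item{head_hd}{`NECK_y - NOSE_y`, pixels; positive while the nose is
#'     above the neck.}
#' }
#' Each feature carries a validity flag; a feature is invalid exactly when a
#' contributing keypoint has confidence below `config$min_confidence` (or
#' the two endpoints coincide). Coordinates of keypoints below the
#' confidence floor are never read, except that a missing MID_HIP is
#' replaced by the midpoint of the two hips when both are valid.
#'
#' @param kp `25 x 3` keypoint matrix (see [frame_keypoints]).
#' @param scale body scale in pixels (> 0), see [body_scale].
#' @param config a [classifier_config].
#' @return One-row `data.frame` with columns `trunk_angle`, `head_angle`,
#'   `hip_line_angle`, `trunk_hd`, `head_hd`, `body_scale`, `trunk_valid`,
#'   `head_valid`, `hip_valid`.
#' @export
compute_features <- function(kp, scale, config = classifier_config()) {
  stopifnot(is.matrix(kp), nrow(kp) == 25, ncol(kp) == 3, scale > 0)
  ok <- kp[, 3] >= config$min_confidence & is.finite(kp[, 1]) &
    is.finite(kp[, 2])

  mh <- effective_mid_hip(kp, ok)
  neck <- kp[kp_row("NECK"), 1:2]
  nose <- kp[kp_row("NOSE"), 1:2]
  lhip <- kp[kp_row("L_HIP"), 1:2]
  rhip <- kp[kp_row("R_HIP"), 1:2]

  seg <- function(a, b) {
    if (all(a == b)) return(NA_real_)  # degenerate -> invalid feature
    segment_vertical_angle(a, b)
  }

  trunk_valid <- !is.null(mh) && ok[kp_row("NECK")]
  trunk_angle <- if (trunk_valid) seg(mh, neck) else NA_real_
  trunk_hd <- if (trunk_valid) height_difference(mh, neck) else NA_real_
  trunk_valid <- trunk_valid && !is.na(trunk_angle)

  head_valid <- ok[kp_row("NECK")] && ok[kp_row("NOSE")]
  head_angle <- if (head_valid) seg(neck, nose) else NA_real_
  head_hd <- if (head_valid) height_difference(neck, nose) else NA_real_
  head_valid <- head_valid && !is.na(head_angle)

  hip_valid <- ok[kp_row("L_HIP")] && ok[kp_row("R_HIP")]
  hip_line_angle <- if (hip_valid) seg(lhip, rhip) else NA_real_
  hip_valid <- hip_valid && !is.na(hip_line_angle)

  data.frame(trunk_angle = trunk_angle, head_angle = head_angle,
             hip_line_angle = hip_line_angle,
             trunk_hd = trunk_hd, head_hd = head_hd,
             body_scale = scale,
             trunk_valid = trunk_valid, head_valid = head_valid,
             hip_valid = hip_valid)
}

#' Per-frame features for a whole sequence
#'
#' Estimates the body scale from the first `config$calibration_frames`
#' frames (via [body_scale]) and applies [compute_features] to every frame.
#' The result is a tidy table, one row per frame, suitable for CSV export
#' and downstream modelling.
#'
#' @param seq a [pose_sequence].
#' @param config a [classifier_config].
#' @param scale optional pre-computed body scale; estimated when `NULL`.
#' @return `data.frame` with a leading `t` column (seconds) and the
#'   [compute_features] columns, `n_frames(seq)` rows.
#' @export
sequence_features <- function(seq, config = classifier_config(),
                              scale = NULL) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- n_frames(seq)
  if (n == 0) {
    dummy <- missing_frame()
    dummy[, 3] <- 1
    return(cbind(data.frame(t = numeric(0)),
                 compute_features(dummy, 1, config)[0, ]))
  }
  if (is.null(scale)) {
    calib <- pose_sequence(
      seq$keypoints[seq_len(min(config$calibration_frames, n)), , ,
                    drop = FALSE],
      seq$timestamps[seq_len(min(config$calibration_frames, n))])
    scale <- body_scale(calib, config)
  }
  rows <- vector("list", n)
  for (i in seq_len(n))
    rows[[i]] <- compute_features(frame_keypoints(seq, i), scale, config)
  cbind(data.frame(t = seq$timestamps), do.call(rbind, rows))
}
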