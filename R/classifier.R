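#' Forward-fall detector methods
#'
#' The three selectable forward-fall criteria, all thresholded height
#' differences between keypoints:
#' \describe{
#'   \item{I_OPOSE}{neck-to-nose height difference — fires when the nose
#'     sits at or below the neck ("head downward"). Fragile when face
#'     keypoints are lost to shadow or dim light.}
#'   \item{E_HN_OPOSE}{waist(mid-hip)-to-neck height difference — fires
#'     when the trunk has collapsed vertically without a lateral lean.
#'     Robust to face loss but blind during the early falling motion.}
#'   \item{E_OPOSE}{the disjunction of the two, exactly; each method covers
#'     the other's failure mode.}
#' }
#' @format Character vector of the three method names.
#' @export
DETECTOR_METHODS <- c("I_OPOSE", "E_HN_OPOSE", "E_OPOSE")

#' Classifier configuration
#'
#' All thresholds are ratios to the subject's [body_scale] (pixels), so one
#' configuration serves near and far camera distances alike. Defaults are
#' this package's calibration of rules whose thresholds the underlying
#' method leaves unstated; every value is exposed here.
#'
#' @param lying_hd_ratio trunk height-difference ratio below which the
#'   trunk counts as collapsed (default 0.35; an upright trunk has ratio
#'   ~1, a horizontal one ~0).
#' @param lateral_angle_deg absolute trunk angle, degrees, beyond which the
#'   lean is lateral (default 45).
#' @param head_down_angle_deg absolute head angle, degrees, beyond which
#'   the head points downward (default 90). Reserved for experimentation;
#'   the default cascade uses `head_hd_ratio` instead.
#' @param head_hd_ratio head height-difference ratio below which the head
#'   counts as down (default 0: the nose at or below the neck).
#' @param min_confidence keypoint confidence floor (default 0.1); below it
#'   a keypoint is treated as missing.
#' @param method forward-fall detector, one of [DETECTOR_METHODS]
#'   (default `"E_OPOSE"`).
#' @param calibration_frames leading frames used to estimate the body
#'   scale (default 10).
#' @param default_scale last-resort body scale in pixels (default 80).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(lying_hd_ratio = 0.35,
                              lateral_angle_deg = 45,
                              head_down_angle_deg = 90,
                              head_hd_ratio = 0,
                              min_confidence = 0.1,
                              method = "E_OPOSE",
                              calibration_frames = 10,
                              default_scale = 80) {
  method <- match.arg(method, DETECTOR_METHODS)
  stopifnot(is.finite(lying_hd_ratio), lying_hd_ratio > 0,
            lying_hd_ratio < 1,
            is.finite(lateral_angle_deg), lateral_angle_deg > 0,
            lateral_angle_deg < 180,
            is.finite(head_down_angle_deg), head_down_angle_deg > 0,
            head_down_angle_deg < 180,
            is.finite(head_hd_ratio),
            min_confidence >= 0, min_confidence <= 1,
            calibration_frames >= 1, default_scale > 0)
  structure(list(lying_hd_ratio = lying_hd_ratio,
                 lateral_angle_deg = lateral_angle_deg,
                 head_down_angle_deg = head_down_angle_deg,
                 head_hd_ratio = head_hd_ratio,
                 min_confidence = min_confidence,
                 method = method,
                 calibration_frames = calibration_frames,
                 default_scale = default_scale),
            class = "classifier_config")
}

#' Forward-fall indicator
#'
#' Evaluates one of the three forward-fall criteria on a frame's features.
#' An invalid contributing feature makes that disjunct `FALSE` (never `NA`):
#' \itemize{
#'   \item `I_OPOSE`: `head_hd < head_hd_ratio * body_scale` — nose at or
#'     below the neck;
#'   \item `E_HN_OPOSE`: `trunk_hd < lying_hd_ratio * body_scale` and
#'     `|trunk_angle| < lateral_angle_deg` — collapsed, non-lateral trunk;
#'   \item `E_OPOSE`: `I_OPOSE | E_HN_OPOSE`, exactly.
#' }
#' The disjunction is what drives the method's robustness: dropped face
#' keypoints disable `I_OPOSE` but leave `E_HN_OPOSE` intact, and vice
#' versa for the early falling motion where the trunk is not yet collapsed.
#'
#' @param features one row of [compute_features] output (or a list with
#'   the same fields).
#' @param config a [classifier_config].
#' @param method one of [DETECTOR_METHODS]; defaults to `config$method`.
#' @return Logical scalar.
#' @export
forward_indicator <- function(features, config = classifier_config(),
                              method = config$method) {
  method <- match.arg(method, DETECTOR_METHODS)
  i_op <- isTRUE(features$head_valid) &&
    features$head_hd < config$head_hd_ratio * features$body_scale
  ehn <- isTRUE(features$trunk_valid) &&
    features$trunk_hd < config$lying_hd_ratio * features$body_scale &&
    abs(features$trunk_angle) < config$lateral_angle_deg
  switch(method, I_OPOSE = i_op, E_HN_OPOSE = ehn, E_OPOSE = i_op || ehn)
}

#' Classify one frame's posture
#'
#' The rule cascade, first match wins:
#' \enumerate{
#'   \item `UNKNOWN` — trunk features invalid and no forward indication:
#'     there is no skeleton evidence to act on;
#'   \item `FALL_RIGHT` — trunk valid, collapsed or lateral
#'     (`trunk_hd < lying_hd_ratio * scale` or
#'     `|trunk_angle| > lateral_angle_deg`), and
#'     `trunk_angle >= +lateral_angle_deg`;
#'   \item `FALL_LEFT` — symmetric, `trunk_angle <= -lateral_angle_deg`;
#'   \item `FALL_FORWARD` — [forward_indicator] fires under
#'     `config$method` and the head does not testify upright (nose visibly
#'     above the neck). The head-up veto is what separates forward from
#'     backward when the collapsed-trunk criterion alone cannot: with the
#'     face visible and above the neck, a collapsed trunk is a backward
#'     fall;
#'   \item `FALL_BACK` — trunk collapsed, not lateral, not forward;
#'   \item `NORMAL` otherwise.
#' }
#' Lateral falls are tested first because the trunk angle identifies them
#' unambiguously; forward and backward share the collapsed-trunk signature
#' and are split by the head cue.
#'
#' @inheritParams forward_indicator
#' @return A posture label, one of [POSTURE_LEVELS].
#' @export
classify_frame <- function(features, config = classifier_config()) {
  collapsed <- isTRUE(features$trunk_valid) &&
    features$trunk_hd < config$lying_hd_ratio * features$body_scale
  lateral <- isTRUE(features$trunk_valid) &&
    abs(features$trunk_angle) > config$lateral_angle_deg
  fwd <- forward_indicator(features, config, config$method)
  head_up <- isTRUE(features$head_valid) &&
    features$head_hd > config$head_hd_ratio * features$body_scale

  if (!isTRUE(features$trunk_valid) && !fwd) return("UNKNOWN")
  if (collapsed || lateral) {
    if (features$trunk_angle >= config$lateral_angle_deg) return("FALL_RIGHT")
    if (features$trunk_angle <= -config$lateral_angle_deg) return("FALL_LEFT")
  }
  if (fwd && !head_up) return("FALL_FORWARD")
  if (collapsed) return("FALL_BACK")
  "NORMAL"
}

#' Classify every frame of a sequence
#'
#' Estimates the body scale from the first `config$calibration_frames`
#' frames (with [body_scale]'s fallback chain) and applies [classify_frame]
#' to each frame.
#'
#' @param seq a [pose_sequence].
#' @param config a [classifier_config].
#' @return Factor of length `n_frames(seq)` with levels [POSTURE_LEVELS].
#' @export
classify_sequence <- function(seq, config = classifier_config()) {
  feats <- sequence_features(seq, config)
  n <- nrow(feats)
  labels <- character(n)
  for (i in seq_len(n)) labels[i] <- classify_frame(feats[i, ], config)
  as_posture_factor(labels)
}
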