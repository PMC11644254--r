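#' Scenario specification for the synthetic skeleton simulator
#'
#' A fully seeded description of one synthetic standing-to-falling-to-lying
#' BODY_25 sequence. The defaults are the benchmark's stated world: 100
#' consecutive frames per trial at 10 fps, a subject of 400 px standing
#' height (the "near" camera distance; "far" uses 240 px), 30 standing
#' frames, a 30-frame fall, then holding the lying pose.
#'
#' @param direction `"FALL_LEFT"`, `"FALL_RIGHT"`, `"FALL_BACK"`,
#'   `"FALL_FORWARD"`, or `"NONE"` for a pure standing sequence.
#' @param n_frames total frame count (default 100).
#' @param fps frame rate in Hz (default 10).
#' @param fall_start_frame 1-based index of the first falling frame
#'   (default 30).
#' @param fall_duration_frames frames spent in the falling motion
#'   (default 30); `fall_start_frame + fall_duration_frames - 1` must not
#'   exceed `n_frames`.
#' @param subject_height_px standing height in pixels — the camera-distance
#'   proxy (default 400).
#' @param noise_sigma_px standard deviation of the i.i.d. Gaussian jitter
#'   added to each surviving keypoint coordinate (default 0).
#' @param dropout named list of per-frame dropout probabilities by keypoint
#'   group: `face` (nose, eyes, ears), `torso`, `arms`, `legs`; missing
#'   entries default to 0.
#' @param conf_range range of the uniform keypoint confidences drawn before
#'   dropout (default `c(0.7, 1)`).
#' @param seed integer seed; generation and corruption are fully
#'   deterministic given the spec.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(direction = "NONE", n_frames = 100, fps = 10,
                          fall_start_frame = 30,
                          fall_duration_frames = 30,
                          subject_height_px = 400,
                          noise_sigma_px = 0,
                          dropout = list(),
                          conf_range = c(0.7, 1),
                          seed = 1) {
  direction <- match.arg(direction, c("NONE", FALL_DIRECTIONS))
  groups <- c("face", "torso", "arms", "legs")
  drop <- stats::setNames(rep(0, 4), groups)
  if (length(dropout)) {
    bad <- setdiff(names(dropout), groups)
    if (length(bad)) stop("unknown dropout groups: ",
                          paste(bad, collapse = ", "))
    drop[names(dropout)] <- unlist(dropout)
  }
  stopifnot(n_frames >= 1, fps > 0, fall_start_frame >= 1,
            fall_duration_frames >= 1,
            direction == "NONE" ||
              fall_start_frame + fall_duration_frames - 1 <= n_frames,
            subject_height_px > 0, noise_sigma_px >= 0,
            all(drop >= 0), all(drop <= 1),
            length(conf_range) == 2, conf_range[1] <= conf_range[2],
            conf_range[1] >= 0, conf_range[2] <= 1)
  structure(list(direction = direction, n_frames = as.integer(n_frames),
                 fps = fps, fall_start_frame = as.integer(fall_start_frame),
                 fall_duration_frames = as.integer(fall_duration_frames),
                 subject_height_px = subject_height_px,
                 noise_sigma_px = noise_sigma_px,
                 dropout = as.list(drop), conf_range = conf_range,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# body proportion table (fractions of standing height H), image convention
.skel_prop <- list(head = 0.12, trunk = 0.30, thigh = 0.25, shin = 0.25,
                   shoulder_w = 0.25, hip_w = 0.15)

#' Canonical upright BODY_25 skeleton
#'
#' An idealized standing pose built from a fixed proportion table
#' (fractions of standing height `H`): head 0.12, trunk 0.30, thigh 0.25,
#' shin 0.25, shoulder width 0.25, hip width 0.15. NOSE sits directly above
#' NECK directly above MID_HIP (trunk angle 0), the hip line is horizontal,
#' and the subject faces the camera so their right side lies on the image
#' left.
#'
#' @param height_px standing height in pixels.
#' @param center_x image x of the body midline (default 320).
#' @param ground_y image y of the ground line (default 460).
#' @return `25 x 2` matrix of `(x, y)` image coordinates, rownames from
#'   [BODY25].
#' @export
canonical_skeleton <- function(height_px, center_x = 320, ground_y = 460) {
  stopifnot(height_px > 0)
  H <- height_px; cx <- center_x; g <- ground_y
  p <- .skel_prop
  # heights above ground
  ankle_y <- g
  knee_y <- g - p$shin * H
  hip_y <- g - (p$shin + p$thigh) * H
  neck_y <- hip_y - p$trunk * H
  nose_y <- neck_y - p$head * H
  # subject's right on image-left (facing the camera)
  R <- function(off) cx - off
  L <- function(off) cx + off
  m <- rbind(
    NOSE = c(cx, nose_y),
    NECK = c(cx, neck_y),
    R_SHOULDER = c(R(p$shoulder_w / 2 * H), neck_y),
    R_ELBOW = c(R(0.16 * H), neck_y + 0.18 * H),
    R_WRIST = c(R(0.17 * H), neck_y + 0.34 * H),
    L_SHOULDER = c(L(p$shoulder_w / 2 * H), neck_y),
    L_ELBOW = c(L(0.16 * H), neck_y + 0.18 * H),
    L_WRIST = c(L(0.17 * H), neck_y + 0.34 * H),
    MID_HIP = c(cx, hip_y),
    R_HIP = c(R(p$hip_w / 2 * H), hip_y),
    R_KNEE = c(R(0.05 * H), knee_y),
    R_ANKLE = c(R(0.05 * H), ankle_y),
    L_HIP = c(L(p$hip_w / 2 * H), hip_y),
    L_KNEE = c(L(0.05 * H), knee_y),
    L_ANKLE = c(L(0.05 * H), ankle_y),
    R_EYE = c(R(0.03 * H), nose_y - 0.02 * H),
    L_EYE = c(L(0.03 * H), nose_y - 0.02 * H),
    R_EAR = c(R(0.06 * H), nose_y - 0.01 * H),
    L_EAR = c(L(0.06 * H), nose_y - 0.01 * H),
    L_BIG_TOE = c(L(0.08 * H), g),
    L_SMALL_TOE = c(L(0.10 * H), g),
    L_HEEL = c(L(0.04 * H), g),
    R_BIG_TOE = c(R(0.08 * H), g),
    R_SMALL_TOE = c(R(0.10 * H), g),
    R_HEEL = c(R(0.04 * H), g))
  stopifnot(identical(rownames(m), names(BODY25)))
  m
}

# rigid in-plane rotation about `center`, angle phi in radians;
# positive phi tips the upright body toward image-right
rotate_points <- function(pts, center, phi) {
  dx <- pts[, 1] - center[1]
  dy <- pts[, 2] - center[2]
  cbind(center[1] + cos(phi) * dx - sin(phi) * dy,
        center[2] + sin(phi) * dx + cos(phi) * dy)
}

# cosine-eased progress through the fall for frame i (1-based)
fall_progress <- function(i, spec) {
  if (spec$direction == "NONE" || i < spec$fall_start_frame) return(0)
  last <- spec$fall_start_frame + spec$fall_duration_frames - 1L
  if (i >= last) return(1)
  p <- (i - spec$fall_start_frame + 1) / spec$fall_duration_frames
  (1 - cos(pi * p)) / 2
}

# kinematic constants of the fall model
.lying_compression <- 0.25  # final vertical foreshortening factor
.face_drop_frac <- 0.20     # forward fall: extra face descent, fraction of H
.lateral_target_deg <- 90   # final trunk angle of a lateral fall
.truth_hd_ratio <- 0.35     # generator's own lying criterion (trunk ratio)
.truth_angle_deg <- 45      # generator's own lying criterion (rotation)

#' Generate a labeled synthetic fall sequence
#'
#' Builds the standing / falling / lying phases from the
#' [canonical_skeleton]:
#' \itemize{
#'   \item lateral falls are a rigid in-plane rotation of the whole
#'     skeleton about the ankle midpoint, easing smoothly (cosine) to
#'     -90 degrees (left) or +90 degrees (right);
#'   \item forward and backward falls — motion out of the image plane —
#'     are modeled as progressive vertical foreshortening of all segment
#'     heights to a factor of 0.25, with the face keypoints additionally
#'     descending in a forward fall so the final pose has the nose below
#'     the neck (head toward the camera); in a backward fall the nose
#'     stays above the neck.
#' }
#' Ground-truth labels come from the generator's own kinematic state, not
#' from any classifier: a frame is labeled with the scenario direction once
#' the generated trunk height-difference drops below 0.35 of the standing
#' trunk length or the rigid rotation exceeds 45 degrees; transition frames
#' before that are `NORMAL`. Keypoint confidences are drawn uniformly from
#' `spec$conf_range`. Fully deterministic given `spec$seed`.
#'
#' @param spec a [scenario_spec].
#' @return A `labeled_sequence`: list with `sequence` (a [pose_sequence])
#'   and `truth` (posture factor, same length).
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  base <- canonical_skeleton(spec$subject_height_px)
  H <- spec$subject_height_px
  trunk_len <- .skel_prop$trunk * H
  g <- base[kp_row("R_ANKLE"), 2]
  ankle_mid <- (base[kp_row("R_ANKLE"), 1:2] +
                  base[kp_row("L_ANKLE"), 1:2]) / 2
  face_rows <- vapply(c("NOSE", "R_EYE", "L_EYE", "R_EAR", "L_EAR"),
                      kp_row, 1L)
  n <- spec$n_frames
  kp <- array(0, c(n, 25, 3))
  truth <- rep("NORMAL", n)
  conf <- withr::with_seed(spec$seed, {
    matrix(stats::runif(n * 25, spec$conf_range[1], spec$conf_range[2]),
           n, 25)
  })
  for (i in seq_len(n)) {
    u <- fall_progress(i, spec)
    pts <- base
    if (spec$direction %in% c("FALL_LEFT", "FALL_RIGHT") && u > 0) {
      sgn <- if (spec$direction == "FALL_RIGHT") 1 else -1
      phi_deg <- sgn * u * .lateral_target_deg
      pts <- rotate_points(base, ankle_mid, phi_deg * pi / 180)
      if (abs(phi_deg) > .truth_angle_deg) truth[i] <- spec$direction
    } else if (spec$direction %in% c("FALL_BACK", "FALL_FORWARD") && u > 0) {
      f <- 1 - (1 - .lying_compression) * u
      pts[, 2] <- g - f * (g - base[, 2])
      if (spec$direction == "FALL_FORWARD")
        pts[face_rows, 2] <- pts[face_rows, 2] + u * .face_drop_frac * H
      hd <- pts[kp_row("MID_HIP"), 2] - pts[kp_row("NECK"), 2]
      if (hd < .truth_hd_ratio * trunk_len) truth[i] <- spec$direction
    }
    kp[i, , 1:2] <- pts
    kp[i, , 3] <- conf[i, ]
  }
  seq <- pose_sequence(kp, timestamps = (seq_len(n) - 1) / spec$fps,
                       metadata = list(source = "synthetic",
                                       direction = spec$direction,
                                       fps = spec$fps, seed = spec$seed))
  structure(list(sequence = seq, truth = as_posture_factor(truth)),
            class = "labeled_sequence")
}

# keypoint group membership for dropout, as 1-based rows
.group_rows <- function() {
  face <- c("NOSE", "R_EYE", "L_EYE", "R_EAR", "L_EAR")
  torso <- c("NECK", "R_SHOULDER", "L_SHOULDER", "MID_HIP", "R_HIP", "L_HIP")
  arms <- c("R_ELBOW", "R_WRIST", "L_ELBOW", "L_WRIST")
  legs <- setdiff(names(BODY25), c(face, torso, arms))
  lapply(list(face = face, torso = torso, arms = arms, legs = legs),
         function(nms) vapply(nms, kp_row, 1L))
}

#' Corrupt a labeled sequence with jitter and keypoint dropout
#'
#' The degradation model for the benchmark conditions: per keypoint per
#' frame, with its group's dropout probability the keypoint is lost
#' (confidence set to 0, coordinates zeroed — the missing-keypoint
#' convention); surviving keypoints get independent Gaussian jitter
#' `N(0, noise_sigma_px^2)` on x and y. Face-concentrated dropout emulates
#' dim lighting, where pose estimators lose above-the-neck keypoints.
#' Truth labels are untouched. Deterministic given `spec$seed` (the
#' corruption stream is seeded at `spec$seed + 1`).
#'
#' @param lseq a `labeled_sequence` from [generate_sequence].
#' @param spec the [scenario_spec] carrying `dropout`, `noise_sigma_px`
#'   and `seed`.
#' @return A `labeled_sequence` of the same shape.
#' @export
apply_noise_and_dropout <- function(lseq, spec) {
  stopifnot(inherits(lseq, "labeled_sequence"),
            inherits(spec, "scenario_spec"))
  kp <- lseq$sequence$keypoints
  n <- dim(kp)[1]
  p_kp <- numeric(25)
  for (grp in names(.group_rows()))
    p_kp[.group_rows()[[grp]]] <- spec$dropout[[grp]]
  withr::with_seed(spec$seed + 1L, {
    u <- matrix(stats::runif(n * 25), n, 25)
    jit <- array(stats::rnorm(n * 25 * 2, 0, max(spec$noise_sigma_px, 0)),
                 c(n, 25, 2))
  })
  dropped <- u < matrix(p_kp, n, 25, byrow = TRUE)
  if (spec$noise_sigma_px > 0)
    kp[, , 1:2] <- kp[, , 1:2] + jit
  for (j in 1:25) {
    kp[, j, 1][dropped[, j]] <- 0
    kp[, j, 2][dropped[, j]] <- 0
    kp[, j, 3][dropped[, j]] <- 0
  }
  seq <- pose_sequence(kp, lseq$sequence$timestamps,
                       lseq$sequence$metadata)
  structure(list(sequence = seq, truth = lseq$truth),
            class = "labeled_sequence")
}

# benchmark condition presets (overrides of scenario_spec defaults)
.scenario_presets <- list(
  clean = list(),
  near = list(noise_sigma_px = 1),
  far = list(subject_height_px = 240, noise_sigma_px = 1),
  normal_light = list(noise_sigma_px = 1, dropout = list(face = 0.05)),
  overexposed = list(noise_sigma_px = 2, dropout = list(face = 0.3)),
  dim = list(noise_sigma_px = 2, dropout = list(face = 0.7)),
  similar_background = list(noise_sigma_px = 1, conf_range = c(0.5, 1)),
  different_background = list(noise_sigma_px = 1, conf_range = c(0.5, 1))
)

#' Benchmark scenario presets
#'
#' Named degradation conditions mirroring the benchmark design:
#' `clean` (no corruption), `near` / `far` (subject height 400 / 240 px —
#' the camera-distance proxy — with 1 px jitter), `normal_light`,
#' `overexposed` (face dropout 0.3), `dim` (face dropout 0.7, the
#' above-the-neck keypoint-loss regime), and `similar_background` /
#' `different_background` (confidences drawn from a wider `(0.5, 1)` range;
#' skeleton input largely abstracts the background away).
#'
#' @param preset preset name; call `scenario_presets()` for the list.
#' @param direction,seed,... passed to [scenario_spec], overriding preset
#'   values.
#' @return `scenario_preset` returns a [scenario_spec];
#'   `scenario_presets` returns the preset names.
#' @export
scenario_preset <- function(preset, direction = "NONE", seed = 1, ...) {
  preset <- match.arg(preset, names(.scenario_presets))
  args <- utils::modifyList(.scenario_presets[[preset]],
                            list(direction = direction, seed = seed, ...))
  do.call(scenario_spec, args)
}

#' @rdname scenario_preset
#' @export
scenario_presets <- function() names(.scenario_presets)
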