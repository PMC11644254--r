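# Independent brute-force oracle for the segment-to-vertical angle:
# magnitude from the dot product of the unit segment vector with the image
# "up" direction (0, -1), sign from the cross product. Never calls the
# package's atan2 path.
oracle_segment_angle <- function(a, b) {
  v <- c(b[1] - a[1], b[2] - a[2])
  v <- v / sqrt(sum(v^2))
  up <- c(0, -1)
  dt <- max(-1, min(1, sum(v * up)))
  mag <- acos(dt) * 180 / pi
  cross <- up[1] * v[2] - up[2] * v[1]  # = v[1]
  if (cross < 0) -mag else mag          # cross == 0 -> +mag (0 or 180)
}

# a standing keypoint matrix with uniform confidence
standing_kp <- function(height = 400, conf = 0.9) {
  pts <- canonical_skeleton(height)
  cbind(pts, confidence = rep(conf, 25))
}

# set named keypoints missing (confidence 0, coords zeroed)
drop_kp <- function(kp, names) {
  for (nm in names) kp[BODY25[[nm]] + 1L, ] <- 0
  kp
}

# reflect a keypoint matrix across the vertical line x = axis_x,
# swapping anatomical left/right slots so the skeleton stays coherent
mirror_kp <- function(kp, axis_x = 320) {
  out <- kp
  out[, 1] <- 2 * axis_x - kp[, 1]
  out[kp[, 3] == 0, 1] <- 0  # keep missing keypoints at the 0,0 convention
  swap <- function(a, b) {
    ia <- BODY25[[a]] + 1L; ib <- BODY25[[b]] + 1L
    tmp <- out[ia, ]; out[ia, ] <<- out[ib, ]; out[ib, ] <<- tmp
  }
  pairs <- list(c("R_SHOULDER", "L_SHOULDER"), c("R_ELBOW", "L_ELBOW"),
                c("R_WRIST", "L_WRIST"), c("R_HIP", "L_HIP"),
                c("R_KNEE", "L_KNEE"), c("R_ANKLE", "L_ANKLE"),
                c("R_EYE", "L_EYE"), c("R_EAR", "L_EAR"),
                c("R_BIG_TOE", "L_BIG_TOE"),
                c("R_SMALL_TOE", "L_SMALL_TOE"), c("R_HEEL", "L_HEEL"))
  for (p in pairs) swap(p[1], p[2])
  out
}

# write an OpenPose-dialect JSON file; people = list of 25x3 matrices
write_openpose_file <- function(people, path, mangle_length = 0) {
  ppl <- lapply(people, function(m) {
    v <- as.numeric(t(m))  # x, y, c interleaved
    if (mangle_length != 0) v <- v[seq_len(length(v) + mangle_length)]
    list(pose_keypoints_2d = v)
  })
  jsonlite::write_json(list(version = 1.3, people = ppl), path,
                       auto_unbox = TRUE, digits = NA)
  path
}

# features for a hand-built frame at a given scale
features_of <- function(kp, scale = 120, config = classifier_config()) {
  compute_features(kp, scale, config)
}
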