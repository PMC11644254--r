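# hand-built feature rows for cascade unit tests (scale 100 px)
feat <- function(trunk_angle = 0, trunk_hd = 100, head_hd = 12,
                 trunk_valid = TRUE, head_valid = TRUE, scale = 100) {
  list(trunk_angle = trunk_angle, head_angle = 0, hip_line_angle = 90,
       trunk_hd = trunk_hd, head_hd = head_hd, body_scale = scale,
       trunk_valid = trunk_valid, head_valid = head_valid, hip_valid = TRUE)
}

test_that("forward_indicator implements the three criteria", {
  cfg <- classifier_config()
  # head-down frame: nose 20 px below the neck
  hd <- feat(trunk_hd = 60, head_hd = -20)
  expect_true(forward_indicator(hd, cfg, "I_OPOSE"))

  # same geometry with the nose dropped: I fails, E_HN catches the
  # collapsed trunk, E inherits it — the complementarity mechanism
  dropped <- feat(trunk_hd = 10, head_hd = NA_real_, head_valid = FALSE)
  expect_false(forward_indicator(dropped, cfg, "I_OPOSE"))
  expect_true(forward_indicator(dropped, cfg, "E_HN_OPOSE"))
  expect_true(forward_indicator(dropped, cfg, "E_OPOSE"))

  # standing: no criterion fires
  st <- feat()
  for (m in DETECTOR_METHODS) expect_false(forward_indicator(st, cfg, m))

  # lateral lean blocks E_HN even with a collapsed trunk
  lat <- feat(trunk_angle = 80, trunk_hd = 10)
  expect_false(forward_indicator(lat, cfg, "E_HN_OPOSE"))
})

test_that("E_OPose is exactly the disjunction of the component methods", {
  cfg <- classifier_config()
  set.seed(404)
  for (i in 1:500) {
    f <- feat(trunk_angle = runif(1, -180, 180),
              trunk_hd = runif(1, -120, 120),
              head_hd = runif(1, -60, 60),
              trunk_valid = runif(1) > 0.2,
              head_valid = runif(1) > 0.2)
    expect_identical(forward_indicator(f, cfg, "E_OPOSE"),
                     forward_indicator(f, cfg, "I_OPOSE") ||
                       forward_indicator(f, cfg, "E_HN_OPOSE"))
  }
})

test_that("classify_frame follows the rule cascade", {
  cfg <- classifier_config()
  # strong lateral lean with collapsed trunk
  expect_equal(classify_frame(feat(trunk_angle = 80, trunk_hd = 10), cfg),
               "FALL_RIGHT")
  expect_equal(classify_frame(feat(trunk_angle = -80, trunk_hd = 10), cfg),
               "FALL_LEFT")
  # collapsed non-lateral trunk with the nose above the neck: backward
  expect_equal(classify_frame(feat(trunk_angle = 5, trunk_hd = 12,
                                   head_hd = 8), cfg),
               "FALL_BACK")
  # collapsed trunk with the head down: forward
  expect_equal(classify_frame(feat(trunk_angle = 5, trunk_hd = 12,
                                   head_hd = -15), cfg),
               "FALL_FORWARD")
  # collapsed trunk, face lost: forward via E_HN under the default method
  expect_equal(classify_frame(feat(trunk_angle = 5, trunk_hd = 12,
                                   head_hd = NA_real_,
                                   head_valid = FALSE), cfg),
               "FALL_FORWARD")
  # upright standing
  expect_equal(classify_frame(feat(trunk_angle = 0, trunk_hd = 90), cfg),
               "NORMAL")
  # no evidence at all
  expect_equal(classify_frame(feat(trunk_valid = FALSE, head_valid = FALSE,
                                   trunk_hd = NA_real_,
                                   head_hd = NA_real_), cfg),
               "UNKNOWN")
  # purity: identical input, identical output
  f <- feat(trunk_angle = 50, trunk_hd = 20)
  expect_identical(classify_frame(f, cfg), classify_frame(f, cfg))
})

test_that("reflecting a frame across a vertical axis swaps left and right", {
  cfg <- classifier_config()
  sp <- scenario_spec("FALL_RIGHT", n_frames = 60, seed = 5)
  ls <- generate_sequence(sp)
  scale <- body_scale(ls$sequence, cfg)
  for (i in seq(1, 60, by = 7)) {
    kp <- frame_keypoints(ls$sequence, i)
    lab <- classify_frame(compute_features(kp, scale, cfg), cfg)
    labm <- classify_frame(compute_features(mirror_kp(kp), scale, cfg), cfg)
    expected <- switch(lab, FALL_RIGHT = "FALL_LEFT",
                       FALL_LEFT = "FALL_RIGHT", lab)
    expect_equal(labm, expected)
  }
})

test_that("classify_sequence labels clean sequences per ground truth", {
  # rightward: NORMAL head, FALL_RIGHT tail
  ls <- generate_sequence(scenario_spec("FALL_RIGHT", seed = 3))
  pred <- classify_sequence(ls$sequence)
  expect_equal(as.character(pred[1:20]), rep("NORMAL", 20))
  mask <- ls$truth != "NORMAL"
  expect_true(all(pred[mask] == "FALL_RIGHT"))

  # standing-only sequence stays NORMAL throughout
  st <- generate_sequence(scenario_spec("NONE", n_frames = 5, seed = 2))
  expect_equal(as.character(classify_sequence(st$sequence)),
               rep("NORMAL", 5))

  # clean forward fall: lying phase is FALL_FORWARD under all three methods
  lf <- generate_sequence(scenario_spec("FALL_FORWARD", seed = 4))
  lying <- lf$truth == "FALL_FORWARD"
  for (m in DETECTOR_METHODS) {
    p <- classify_sequence(lf$sequence, classifier_config(method = m))
    expect_true(all(p[lying] == "FALL_FORWARD"),
                label = paste("lying phase all forward under", m))
  }

  # empty sequence -> empty output
  empty <- pose_sequence(array(0, c(0, 25, 3)), numeric(0))
  expect_length(classify_sequence(empty), 0)
})
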