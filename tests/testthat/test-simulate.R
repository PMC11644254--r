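test_that("the canonical skeleton honours the proportion table", {
  m <- canonical_skeleton(400)
  trunk <- unname(m["MID_HIP", 2] - m["NECK", 2])
  expect_equal(trunk, 120)  # 0.30 * 400
  expect_equal(segment_vertical_angle(m["MID_HIP", ], m["NECK", ]), 0)
  expect_equal(segment_vertical_angle(m["NECK", ], m["NOSE", ]), 0)
  expect_equal(abs(segment_vertical_angle(m["L_HIP", ], m["R_HIP", ])), 90)
  expect_equal(unname(m["NECK", 2] - m["NOSE", 2]), 0.12 * 400)
  expect_equal(unname(abs(m["L_HIP", 1] - m["R_HIP", 1])), 0.15 * 400)
  expect_equal(unname(abs(m["L_SHOULDER", 1] - m["R_SHOULDER", 1])),
               0.25 * 400)
})

test_that("generated sequences satisfy the kinematic targets", {
  # rightward fall ends rigidly rotated to +90 degrees
  ls <- generate_sequence(scenario_spec("FALL_RIGHT", seed = 8))
  kp <- frame_keypoints(ls$sequence, 100)
  ang <- segment_vertical_angle(kp["MID_HIP", 1:2], kp["NECK", 1:2])
  expect_equal(ang, 90, tolerance = 1e-6)

  lsl <- generate_sequence(scenario_spec("FALL_LEFT", seed = 8))
  kpl <- frame_keypoints(lsl$sequence, 100)
  expect_equal(segment_vertical_angle(kpl["MID_HIP", 1:2], kpl["NECK", 1:2]),
               -90, tolerance = 1e-6)

  # forward fall ends with the nose below the neck; backward does not
  lsf <- generate_sequence(scenario_spec("FALL_FORWARD", seed = 8))
  kpf <- frame_keypoints(lsf$sequence, 100)
  expect_gt(kpf["NOSE", 2], kpf["NECK", 2])
  lsb <- generate_sequence(scenario_spec("FALL_BACK", seed = 8))
  kpb <- frame_keypoints(lsb$sequence, 100)
  expect_lt(kpb["NOSE", 2], kpb["NECK", 2])
  # foreshortening: final trunk height ratio is the 0.25 compression factor
  expect_equal(unname(kpb["MID_HIP", 2] - kpb["NECK", 2]) / 120, 0.25,
               tolerance = 1e-9)

  # a NONE scenario is all-NORMAL standing
  lsn <- generate_sequence(scenario_spec("NONE", n_frames = 30, seed = 8))
  expect_true(all(lsn$truth == "NORMAL"))
})

test_that("truth labels flip at the generator's kinematic criterion", {
  ls <- generate_sequence(scenario_spec("FALL_RIGHT", seed = 9))
  truth <- as.character(ls$truth)
  # NORMAL head, contiguous FALL_RIGHT tail, nothing else
  flip <- which(truth == "FALL_RIGHT")[1]
  expect_false(is.na(flip))
  expect_true(all(truth[seq_len(flip - 1)] == "NORMAL"))
  expect_true(all(truth[flip:length(truth)] == "FALL_RIGHT"))
  # the flip happens inside the fall window, not before
  expect_gte(flip, 30)
})

test_that("generation and corruption are bit-deterministic under the seed", {
  sp <- scenario_preset("dim", direction = "FALL_FORWARD", seed = 123)
  a <- apply_noise_and_dropout(generate_sequence(sp), sp)
  b <- apply_noise_and_dropout(generate_sequence(sp), sp)
  expect_identical(a$sequence$keypoints, b$sequence$keypoints)
  expect_identical(a$truth, b$truth)

  sp2 <- scenario_preset("dim", direction = "FALL_FORWARD", seed = 124)
  c_ <- apply_noise_and_dropout(generate_sequence(sp2), sp2)
  expect_false(identical(a$sequence$keypoints, c_$sequence$keypoints))
})

test_that("dropout hits at the configured group rates", {
  # certain face dropout: every NOSE is missing
  sp <- scenario_spec("NONE", n_frames = 20, dropout = list(face = 1),
                      seed = 10)
  ls <- apply_noise_and_dropout(generate_sequence(sp), sp)
  expect_true(all(ls$sequence$keypoints[, BODY25[["NOSE"]] + 1L, 3] == 0))
  # non-face groups untouched
  expect_true(all(ls$sequence$keypoints[, BODY25[["NECK"]] + 1L, 3] > 0))

  # all-zero corruption is the identity
  sp0 <- scenario_spec("FALL_LEFT", seed = 10)
  ls0 <- generate_sequence(sp0)
  expect_identical(apply_noise_and_dropout(ls0, sp0)$sequence$keypoints,
                   ls0$sequence$keypoints)

  # binomial concentration at rate 0.5 over 1000 frames
  sp5 <- scenario_spec("NONE", n_frames = 1000,
                       dropout = list(face = 0.5), seed = 11)
  ls5 <- apply_noise_and_dropout(generate_sequence(sp5), sp5)
  frac <- mean(ls5$sequence$keypoints[, BODY25[["NOSE"]] + 1L, 3] == 0)
  expect_gte(frac, 0.45)
  expect_lte(frac, 0.55)
})

test_that("generator output always satisfies the pose-frame invariants", {
  # pose_sequence() validates on construction; exercise varied scenarios
  for (d in c("NONE", FALL_DIRECTIONS)) {
    sp <- scenario_preset("dim", direction = d, seed = 12,
                          n_frames = 40, fall_start_frame = 10,
                          fall_duration_frames = 20)
    ls <- apply_noise_and_dropout(generate_sequence(sp), sp)
    expect_s3_class(ls$sequence, "pose_sequence")
    expect_equal(length(ls$truth), n_frames(ls$sequence))
    conf <- ls$sequence$keypoints[, , 3]
    expect_true(all(conf >= 0 & conf <= 1))
  }
  # invalid spec is rejected
  expect_error(scenario_spec("FALL_LEFT", n_frames = 20,
                             fall_start_frame = 15,
                             fall_duration_frames = 10))
})
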