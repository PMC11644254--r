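Package: fallsense
Title: Rule-Based Fall Posture Analysis from 2D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Detects falls and their direction from OpenPose-style BODY_25
    keypoint streams. Computes geometric posture features (segment-to-vertical
    angles and keypoint height differences), classifies each frame into one of
    four camera-frame fall directions with three selectable forward-fall
    criteria, aggregates frames into fall events with duration-based severity,
    normalizes image brightness by percentile-clipped min-max stretching, and
    ships a seeded synthetic skeleton-sequence simulator plus an evaluation
    harness for method comparison under distance, lighting and keypoint-dropout
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
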