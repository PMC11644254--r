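---
title: "Rule-based fall posture analysis from 2D pose keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based fall posture analysis from 2D pose keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallsense)
```

## The problem

Camera-based fall monitoring for care recipients — from fixed cameras or a
following drone — typically runs a 2D pose estimator (OpenPose's BODY_25
skeleton) on each frame and must then decide, from 25 noisy keypoints, whether
the person has fallen, in which direction, and how serious the fall appears to
be. `fallsense` implements that decision layer: it consumes OpenPose-style
keypoint JSON (it never runs the network itself) and produces per-frame
posture labels, fall events with durations, and severity grades.

The pixel geometry of a fall is direction-dependent. A **lateral** fall tips
the whole body in the image plane, so the trunk segment acquires a large angle
to the vertical axis. A **forward or backward** fall moves the body out of the
image plane toward or away from the camera; in 2D this appears as vertical
*foreshortening* — the height difference between the mid-hip and the neck
collapses — and the two are distinguished by where the head ends up: in a
forward fall the nose descends to or below the neck, in a backward fall it
stays above.

## Features

Two primitives generate every feature:

* `segment_vertical_angle(A, B)` — the angle between the segment joining two
  keypoints and the image's vertical axis, computed as
  `degrees(atan2(A_h - B_h, A_w - B_w) - pi/2)` and wrapped to (-180, 180]
  (an exact raw -180 maps to +180, keeping lateral signs symmetric). With
  image coordinates (y grows downward) the angle is 0 for an upright
  segment, positive when the top end leans toward the image right, and
  +/-90 when horizontal.
* `height_difference(A, B)` — `A_h - B_h` in pixels.

From these, `compute_features()` derives per frame: the trunk angle and
height difference (MID_HIP to NECK), the head angle and height difference
(NECK to NOSE), and the hip-line angle (L_HIP to R_HIP; computed and
exported, but not used by the default rules — it is a direction cue whose
decision rule is left to experimentation). A keypoint below the confidence
floor invalidates every feature it contributes to; a missing MID_HIP is
replaced by the midpoint of the two hips when both are visible, matching the
BODY_25 topology where MID_HIP is itself a derived joint.

### Distance invariance via body scale

Pixel thresholds cannot be constants when the camera distance varies. All
thresholds are therefore expressed as ratios to a per-subject **body scale**:
the median trunk length over a short calibration window (default 10 frames),
falling back to twice the hip width, then to a configured
`default_scale = 80` px. One configuration thus serves near and far subjects
alike; the simulator's near/far presets (400 px vs 240 px standing height)
exercise exactly this.

## The classifier

`classify_frame()` applies a cascade, first match wins:

1. **UNKNOWN** — no valid trunk features and no forward indication. An
   explicit abstention label: without skeleton evidence the classifier must
   not fabricate a direction.
2. **FALL_RIGHT / FALL_LEFT** — the trunk is collapsed
   (`trunk_hd < lying_hd_ratio * scale`) or lateral
   (`|trunk_angle| > lateral_angle_deg`), and the trunk angle is beyond
   the lateral threshold on that side. Lateral falls are tested first
   because the trunk angle identifies them unambiguously.
3. **FALL_FORWARD** — the selected forward indicator fires (below) *and*
   the head does not testify upright. The veto matters: the waist-to-neck
   criterion alone cannot tell forward from backward, so when the face is
   visible and the nose is clearly above the neck, a collapsed trunk is
   read as backward instead.
4. **FALL_BACK** — collapsed trunk, not lateral, not forward.
5. **NORMAL** otherwise.

Left/right are **camera-frame** directions: pixel geometry alone cannot
recover the subject's own left/right without knowing their facing, so a trunk
tipping toward the image's left edge is `FALL_LEFT`.

### The three forward-fall detectors

`forward_indicator()` implements three selectable criteria whose comparison
is the package's built-in method benchmark:

* **I_OPOSE** — `head_hd < head_hd_ratio * scale`: the nose at or below the
  neck. Reads the face, so it fails when dim light or shadow makes the pose
  estimator drop above-the-neck keypoints.
* **E_HN_OPOSE** — `trunk_hd < lying_hd_ratio * scale` with a non-lateral
  trunk: reads the body trunk, immune to face loss, but blind during the
  early falling motion when the trunk has not yet collapsed, and vulnerable
  to torso keypoint occlusion.
* **E_OPOSE** — the disjunction of the two, *exactly*. Because it is a
  logical OR on the same frame, its forward-fall recall is provably at least
  that of either component on any identical input set — the test suite
  asserts the identity frame by frame and the recall ordering on the dim
  benchmark.

### Default thresholds

The thresholds are this package's calibration — the method they implement
describes the rules but publishes no numeric cutoffs — and all are exposed in
`classifier_config()`:

| parameter | default | units | meaning |
|---|---|---|---|
| `lying_hd_ratio` | 0.35 | ratio | trunk HD below this fraction of body scale = collapsed (upright ~ 1, horizontal ~ 0) |
| `lateral_angle_deg` | 45 | degrees | trunk angle beyond this = lateral lean |
| `head_hd_ratio` | 0 | ratio | head HD below this fraction = head down (nose at/below neck, the literal "head downward" reading) |
| `min_confidence` | 0.1 | — | keypoint confidence floor; below it a keypoint is missing |
| `calibration_frames` | 10 | frames | leading window for the body-scale estimate |
| `default_scale` | 80 | px | last-resort body scale |

0.35 sits midway between the simulator's lying compression (trunk ratio
0.25) and the smallest upright ratios seen under jitter, and 45 degrees is
the natural half-way split between upright and horizontal; both margins are
co-designed with the generator (below) so that clean sequences classify
perfectly — a designed guarantee, not an empirical discovery.

## Events and severity

`track_events()` smooths per-frame labels into fall events with a debounced
state machine: an event opens after `onset_frames = 3` consecutive fall
labels (timed from the first of them) and closes at the last fall frame
before `release_frames = 5` consecutive `NORMAL` frames, or at sequence end.
Single-frame estimator flicker therefore never spawns or kills an event.
`UNKNOWN` inside an open event is treated as continuation — occlusion during
a fall must not end it — while outside an event it breaks an onset run. The
event's direction is the modal fall label over its frames (ties to the
earliest observed), absorbing transition-frame misfires.

Severity is graded from duration — a proxy for the person being unable to
get up: `SEVERE` at or beyond `severe_after_s = 8` seconds, `MODERATE`
below. The two-level grading with a single configurable breakpoint
implements the observed moderate/severe escalation; no published cutoff
exists, so 8 s is this package's choice and is plainly a config knob.

Timestamps are synthesized as `frame_index / fps` when reading OpenPose
JSON, since that format carries none; `fps` (default 10) is a required
config item rather than a constant because capture frame rates vary by
platform.

## Brightness normalization

Dim scenes are the dominant failure mode of the face-reading forward
detector. `normalize_brightness()` implements percentile-clipped min–max
stretching, per RGB channel independently: with `lo`/`hi` the 1st/99th
percentile values of the channel (linear interpolation between order
statistics, `quantile type 7`), pixels are clipped to `[lo, hi]` and mapped
affinely to `[out_min, out_max] = [10, 245]`, rounded half-up. The output
bounds sit inside [0, 255] to avoid saturating the 8-bit range. A constant
channel maps to `out_min` (the degenerate `hi == lo` branch). Rounding and
percentile definitions are pinned so two implementations agree bit for bit.

File I/O uses plain ASCII PNM (P2/P3): the environment provides no R PNG or
JPEG codec, and a text format keeps fixtures and outputs inspectable; the
normalization itself operates on ordinary numeric matrices/arrays, so any
image source can be adapted.

## The synthetic simulator

No public dataset of drone-captured falls with BODY_25 annotations exists,
so the test substrate is `generate_sequence()`: seeded, fully deterministic
standing-falling-lying sequences built from a canonical skeleton with fixed
body proportions (head 0.12 H, trunk 0.30 H, thigh and shin 0.25 H each,
shoulder width 0.25 H, hip width 0.15 H).

* **Lateral falls** are a rigid in-plane rotation about the ankle midpoint,
  cosine-eased to +/-90 degrees over the fall window (default 30 frames of a
  100-frame, 10 fps sequence — one benchmark trial is 100 consecutive
  frames).
* **Forward/backward falls** are modeled as vertical foreshortening of all
  segment heights to a factor 0.25, the forward case adding face descent so
  the final nose sits below the neck. This is deliberately *not* a 3D
  projection model: the classifier only sees 2D geometry, and foreshortening
  plus head/feet ordering are precisely the two cues the detectors read.
* **Corruption** (`apply_noise_and_dropout()`): per-keypoint Gaussian jitter
  and per-group dropout (confidence zeroed). The `dim` preset concentrates
  dropout on the face group at probability 0.7 — emulating the empirical
  failure mode where pose estimators lose above-the-neck keypoints in dim
  light — with 2 px jitter; `near`/`far` vary subject height (400/240 px);
  the background presets only widen the confidence range, since skeleton
  input largely abstracts the background away.

Ground-truth labels come from the generator's *kinematic state* — trunk HD
ratio below 0.35 or rigid rotation beyond 45 degrees — never from the
classifier, so truth stays independent of the system under test. Transition
frames before the criterion fires are labeled `NORMAL`; accordingly the
evaluator scores direction accuracy on lying-phase frames only (an
`include_transition` flag widens it), because the question scored is whether
the direction of an actual fall is identified, not when the transition is
first flagged.

What a green synthetic test does **not** establish: performance on real
footage. The simulator has no limb self-occlusion structure, no perspective
distortion, no camera motion, no multi-person scenes, and its dropout is
independent across frames where real estimators fail in bursts. It
establishes parameter recovery (the rules recover the geometry the generator
states) and the structural claims (method dominance, degradation under face
dropout), which is what a desk-scale benchmark can honestly claim.

## Numerical choices and degenerate inputs

* Angle wrap (-180, 180], exact -180 mapping to +180; coincident keypoints
  raise a degenerate-geometry error at the primitive level and are mapped to
  an invalid feature by `compute_features()`.
* Invalid features make classifier disjuncts false, never `NA`.
* Multi-person frames: the person with the highest mean keypoint confidence
  wins, ties to the first listed — deterministic and free of any face
  tracking dependency.
* Sequence and event-log serialization uses 17 significant digits, so
  round-trips are field-exact and identical runs are byte-identical.
* Per-sequence benchmark seeds are `seed + sequence_index`, shared across
  methods so method comparisons always score identical corrupted inputs.

## Limitations

Sitting, crouching and getting-up postures are out of scope (a slow sit can
momentarily satisfy the collapsed-trunk criterion); only one person is
classified per frame; camera-frame left/right cannot be mapped to the
subject's own left/right without facing information; and the severity grade
is a duration proxy, not an injury model.
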