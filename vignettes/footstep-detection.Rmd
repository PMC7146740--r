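---
title: "Registering footsteps in contact regions from frontal video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering footsteps in contact regions from frontal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Reactive-agility training presents a player with a tactical stimulus and
measures two things: whether the player ran to the correct target, and how
long the response took.  The training platform is a 3 x 3 grid of floor
targets spaced 2 m apart; the player starts on the central target (target
5), sprints to the peripheral target the stimulus calls for, and returns
to the centre to trigger the next stimulus.  `agilitrack` registers these
responses from a single frontal camera — no on-body sensors, markers or
instrumented floor — by detecting the exact video frame in which a foot
lands inside a target's *contact region*, the disk of radius 30 cm around
its centre.

The pipeline has four stages, run per frame:

1. **Segmentation.**  A per-pixel Gaussian-mixture background model
   classifies foreground; a scenario mask restricts attention to the
   platform; morphological opening/closing and a minimum-blob filter clean
   the mask.  The player silhouette is the largest connected component, and
   the feet region of interest is the bottom 20% of its bounding box.
   Inside that box, two components of comparable area mean the feet are
   separated; a single component is a self-occlusion (feet crossing in the
   camera view), whose merged box is split vertically in half so each
   foot's filter stays anchored.  Each foot's measurement is its box's
   bottom-centre — the point that touches the floor — plus the box size.

2. **Tracking.**  One linear Kalman filter per foot with state
   $x = [x, y, v_x, v_y, w, h]$ (pixels and pixels/frame), constant-velocity
   transition ($A$ is the identity plus $A_{1,3} = A_{2,4} = \Delta t$,
   with $\Delta t = 1$ frame) and a measurement matrix selecting
   $(x, y, w, h)$.

3. **Step decision.**  Every frame, the Euclidean distance $d$ between the
   predicted and measured box position is tested against two thresholds.
   If $d > \theta_{move}$ the foot is moving: the filter is reset at the
   measurement with zero velocity and the frame is classified `MOVING`.
   Otherwise the filter is updated, and if the post-update distance to the
   measurement is within $\theta_{step}$ the frame is a `STEP`.  A ground
   contact lasts 2–4 frames at 20 fps, during which the foot is static, so
   a contact produces a short run of `STEP` decisions; the debouncer
   collapses each run into one step event at the run's first `STEP` frame.

4. **Contact-region matching and session logic.**  The event's pixel point
   maps to metric floor coordinates through the calibration homography.
   If the nearest target centre is strictly closer than 30 cm the footstep
   *reaches* that target.  Reaching the expected target resolves the
   active play `POSITIVE` (response time = event time − stimulus
   presentation time); reaching a different peripheral target resolves it
   `MISTAKEN`; returning to the central target without having reached any
   peripheral target registers `MISSED`.

## Coordinates and calibration

Pixels are 0-based with the origin at the image top-left and $x$ along
columns.  Platform coordinates are metres, origin at the centre of target
5, $+Y$ toward the camera, $+X$ toward the camera's right.  Target rows
are numbered from the camera outward: 1–3 nearest, 7–9 farthest.

The pixel-to-platform map is a planar homography fitted by the direct
linear transform with Hartley normalisation from at least four
point correspondences (`estimate_homography()`); with more points the fit
is least squares and the RMS reprojection residual is reported.  The
homography is exact only for points on the floor plane: anything above it
(a lifted foot, the torso) maps too far from the camera.  This is the
fundamental single-camera ambiguity of the setup — depth along $-Y$ and
height above the floor are confounded — and it shapes several design
choices below.

## Tunable parameters

All parameters live in one list (`agility_config()`), scale with frame
width where they are in pixels, and can be overridden from a YAML file.

| parameter | default (640 px) | meaning |
|---|---|---|
| `theta_move` | 3 px | reset (moving) threshold on $d$ |
| `theta_step` | 1.5 px | step threshold on the post-update distance |
| `min_gap` | 6 frames | debounce gap between events of one foot |
| `debounce_break` | 10 px | spatial run break (one contact = one place) |
| `min_run` | 2 | `STEP` decisions required to emit an event |
| `seg_threshold` | 16 | squared-Mahalanobis match threshold (the segmentation threshold) |
| `seg_alpha` | 0.025 | mean/variance learning rate |
| `seg_alpha_w` | 0.001 | component-weight learning rate |
| `seg_cf` | 0.6 | cumulative weight defining the background set |
| `seg_var_init`, `seg_var_min`, `seg_var_max` | 4e-4, 2e-4, 9e-4 | variance seed, floor, cap (intensity² in [0,1]) |
| `kalman_P0`, `kalman_Q`, `kalman_R` | diag(10,10,25,25,10,10); diag(1,1,1,1,.5,.5); diag(4,4,4,4) | filter covariances (px²) |

Why these values — the cases where the obvious choice failed:

* **Step thresholds.**  The natural first guess (about 15 px / 4 px at
  640 px width) fails because pixel scale is strongly anisotropic: motion
  toward the far row of targets projects at only ~25 px/m, so a 4 m/s
  sprint moves a foot 3–5 px/frame there, while a genuinely planted foot
  jitters 0–2 px.  Any `theta_move` above the sprint displacement lets the
  filter track a smooth swing and fire steps continuously.  The working
  discriminator is "displacement indistinguishable from zero":
  `theta_move` = 3 px, `theta_step` = 1.5 px.  Because a `MOVING` decision
  re-anchors the filter at the *current* measurement, $d$ is the true
  one-frame displacement on the following frame, and a contact as short as
  two frames still fires a step on its second frame.

* **Debouncing.**  Near the far targets the approach decelerates through
  displacements that hover around `theta_move`, which can chain successive
  footsteps into one run timed at the first stride.  A contact happens at
  one place, so a run additionally breaks when the measured position
  drifts more than `debounce_break` from the run's anchor.  Conversely a
  swinging foot is momentarily stationary at the reversal point of a
  change of direction — off the ground, hence mapped spuriously deep —
  for a single frame; real contacts span 2–4 frames, so an event requires
  `min_run = 2` step decisions.  At the region level, one contact disk
  cannot be genuinely re-stepped within half a second, so same-target
  registrations closer than twice the debounce gap collapse
  (`detected_event_table()`).

* **Background model.**  Three standard parameterisations failed in ways
  worth recording.  (i) A single learning rate cannot both track a slow
  10% illumination drift (which needs fast means) and resist absorbing a
  player who occupies the central pixels a third of the session (which
  needs slow weights); the model therefore decouples them
  (`seg_alpha` vs `seg_alpha_w`).  (ii) With the textbook background
  fraction 0.9, any component reaching weight 0.1 joins the background
  set, so a standing player is absorbed within seconds; 0.6 makes the
  background essentially the majority component.  (iii) Unbounded variance
  adaptation lets a single component's match radius grow until it spans
  the background-to-player contrast, after which the component swallows
  both modes (its mean drifts between them and the silhouette develops
  holes); the variance cap `seg_var_max` = 9e-4 (sd 0.03 in [0,1]
  intensity) keeps the 4-sigma match radius at 0.12, well below the
  ~0.3 contrast.  A grayscale shadow heuristic (proportional darkening at
  0.5–0.95 of the dominant component's mean) suppresses soft shadows and,
  usefully, the downward phase of illumination drift.

* **Occlusion.**  The split-in-half measurement keeps both filters anchored
  through feet crossings instead of coasting them; target matching does
  not depend on foot identity, so identity swaps during occlusion are
  harmless.  Which half is which foot is by horizontal order.  In the
  pipeline, each half's bottom is refined to the lowest foreground row
  within its own columns rather than the merged box's shared bottom:
  when the feet merge while standing at different depths (a far-row
  landing with the trailing foot nearer the camera), the shared bottom
  would read the nearer foot's ground row for both and the landing's
  depth would be unobservable.

* **Missed-play registration.**  A centre match registers `MISSED` only
  once the play is *engaged* (some non-centre footstep has occurred since
  the stimulus): the player is still standing on target 5 when each
  stimulus appears, and without this rule the stand itself would resolve
  the play.  Either foot may resolve a play; ties within a frame go to the
  smaller centre distance, then the left foot.  A mistaken play is assumed
  to require the same centre return as a positive one before the next
  stimulus activates.

## The synthetic session generator

Real recordings of training sessions are not distributable, so the test
bed is synthetic and fully scripted, with exact ground truth.  The
generator emulates the reference recording conditions: 640 x 480 at
20 fps, a pinhole camera 6.5 m in front of the central target at 3.5 m
height (focal length 600 px, chosen so the platform and a 1.85 m player
fill the frame), nine routines of twenty stimuli.  Outcomes are scripted
per play: `POSITIVE` lands inside the expected region (uniform jitter up
to 0.18 m from the centre), `MISTAKEN` inside a wrong region, `MISSED`
30–45 cm from the intended centre, with probabilities 0.82 / 0.10 / 0.08.

The player model is deliberately minimal but kinematically honest where
the detector cares:

* the body follows straight centre → landing → centre paths with a
  trapezoidal speed profile (6 m/s² acceleration, 4 m/s cruise), a
  uniform 0.4–0.7 s reaction delay after each stimulus, and a 3-frame
  stimulus-activation latency after each centre return;
* feet alternate plants (frozen 3 frames; scripted contacts exactly
  `contact_frames` frames) and smoothstep swings with a 0.12 m parabolic
  lift; mid-sprint plants are kept at least 0.5 m from every target
  centre; the trailing foot brakes *behind* the landing in an uncrossed
  shoulder-width stance; standing positions jitter play to play;
* frames are a textured static background, the player as torso + legs +
  foot ellipses (feet drawn on the floor plane, so the ground-plane
  homography is exact for them; the body above is an explicit
  simplification), multiplicative sinusoidal illumination drift (10%,
  30 s period), two drifting soft shadow blobs (10% darkening), additive
  Gaussian sensor noise (sd 0.015) and salt-and-pepper noise (rate 0.001),
  all reproducible from the seed with random access by frame.

Ground truth records per-frame foot positions (metric and pixel), phase
labels, and the scripted event log the evaluation scores against.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real video: articulated limbs and apparel, motion
blur, camera jitter, other people in frame, cast shadows attached to the
player, grass or gym-floor texture change, and genuinely human gait
variability.  The noise processes are statistically stationary
caricatures.  Results on the synthetic campaign establish that the
algorithm logic is sound under the stated geometry and noise regime, not
that these exact metrics transfer to field recordings.

## Evaluation protocol

Detected contact-region events are matched per play to ground-truth
events, greedily, one to one: a true positive names the same target
within 250 ms (`floor(0.250 * fps)` frames — 5 at 20 fps; ties go to the
smallest frame difference, then the earlier frame).  Unmatched detections
are false positives, unmatched ground-truth events false negatives, and a
play with no ground-truth event and no detection is a true negative.
Precision, sensitivity, specificity and F1 follow the usual definitions,
with undefined ratios reported as `NA`.  Per-target timing error is the
mean absolute and the standard deviation of the signed detection-time
error among matched pairs.

The packaged campaign (`run_campaign()`) runs nine synthetic routines —
about 13,000 frames — through the full pipeline and scores them pooled;
it takes a few minutes on one CPU.  The threshold-sweep helper re-runs a
reduced campaign (two routines of ten stimuli by default) at several
segmentation thresholds; precision stays nearly flat across the sweep
while sensitivity varies, reproducing the qualitative robustness shape.
The test suite uses 3–4-stimulus sessions for end-to-end properties and
the full campaign once for the headline metrics.

## Known limitations

* Everything inherits the single-camera depth/height ambiguity: timing
  and position errors concentrate on the far row (targets 7–9), where one
  pixel of row error is ~4 cm of depth.  The per-target error table makes
  this visible.
* The largest-component rule for the silhouette assumes one person in the
  scenario mask.
* Left/right foot identity is positional per frame; it swaps freely
  during crossings.
* The background model needs a short player-free warm-up (the generator
  provides 50 frames); starting cold with the player in frame leaves a
  ghost until the weights adapt.
* Response *time* is measured from stimulus presentation to the resolving
  footstep; the perceptual reaction component is not separated out.
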