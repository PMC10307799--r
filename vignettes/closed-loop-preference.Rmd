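---
title: "Closed-loop social preference: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop social preference: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebrapref)
```

zebrapref re-creates, entirely in software, a closed-loop place-preference
experiment for zebrafish: an animated conspecific ("stimulus fish") is shown
on a monitor at each end of a 45 x 15 cm aquarium, its on-screen motion is
recomputed 30 times per second from the tracked 3D position of the
experimental fish, and preference is scored as the time spent near one
stimulus relative to the other. Because the experimental subject here is a
simulated agent rather than an animal, every downstream stage — controllers,
schedule, scoring, statistics — can be exercised, property-tested, and used
for parameter-recovery studies at will. This vignette documents the models,
the parameters that matter, and the choices made where the design was
genuinely open.

## The world and its coordinate systems

All world coordinates are tank-anchored centimetres (`x` along the 45-cm
length, `y` across the 15-cm width, `z` up from the floor with the water
surface at 11 cm). Three frames are connected by `world_geometry()`:

* **Compartments.** The tank length is split into three equal 15-cm
  compartments. Assignment uses half-open intervals (`[0,15)` left,
  `[15,30)` center, `[30,45]` right) so boundary points have a
  deterministic label: `x = 15` is center, `x = 30` is right.
* **Monitors.** Each 15 x 8.5 cm screen sits flush against a short wall
  with its top edge at the water line. The physical pixel pitch is not a
  published quantity; the default 68.27 px/cm (1024 px across 15 cm) is
  chosen so that the fleeing-trigger thresholds of 350 and 150 px
  correspond to about 5.1 and 2.2 cm, matching their stated physical
  meaning. `u` runs from each monitor's *own* left edge, which makes the
  left and right projections of one fish mirror images
  (`u_L + u_R = width`) and lets a single controller implementation serve
  both screens. Projection drops `x` (the fish and the animation are
  treated as lying in the same plane) and maps `v = (11 - z) * s`. Note the
  bottom 2.5 cm of the water column projects below the screen; the pursuit
  law aims at the projected point while the stimulus position itself is
  clamped to the screen.
* **Camera.** The overhead color+depth camera is modelled as a fixed-scale
  affine map: 640 px span 48 cm with the tank centered (13.33 px/cm), and
  the depth reading is 0.40 m (camera height over the surface) plus the
  submersion depth. No lens distortion or refraction is modelled; the
  published apparatus does not provide intrinsics, and nothing downstream
  depends on them.

## Stimulus controllers

Six motion programs update once per 1/30 s frame (`controller_params()`):

* **Motionless** draws a fresh offset of 0–2 px, left or right, from the
  monitor center each frame. It is an offset *from center*, not a random
  walk: the published description anchors the fish at the center, and a
  cumulative walk would drift.
* **Chasing** moves toward the projected head whenever the head-to-head
  pixel distance `d` exceeds 16 px (strict: `d = 16` does not move), at
  speed `d / 650`. The published rule gives the divisor but not the time
  unit; interpreted as px per millisecond, the per-frame step is
  `d * dt * 1000 / 650 ≈ d / 19.5`, which yields life-like approach speeds
  (≈7 cm/s at 4–5 cm separation) and the documented profile — fastest at
  onset, slowing smoothly into the deadband with no overshoot (the step
  never exceeds `d`). Against a stationary target the distance follows the
  closed form `d_k = d_0 (1 − dt·1000/650)^k`, which the test suite checks
  to 10⁻⁶ relative error.
* **Flipped** is chasing of the left/right mirrored target — identical
  deadband and velocity law; the trajectory is frame-exactly the u-mirror
  of chasing. (Its published description ends by referencing the wrong
  sibling program — "the other features of fleeing" — but it is introduced
  as the mirror image of chasing, and that is what is implemented.)
* **Fleeing** idles until the projected head comes within 350 px
  horizontally *and* 150 px vertically (inclusive, reading "within" as ≤),
  then draws a uniform random target on the opposite monitor half and
  travels there under the same velocity law (no deadband) until within
  1 px. New triggers are ignored while a relocation is in progress, which
  prevents target churn; the published description does not specify
  re-arming. A teleport variant sits behind `flee_teleport` for
  sensitivity checks.
* **Independent** replays a recorded track (`record_playback()`): four
  donor chasing sessions with fish that never serve in the experiment,
  replayed in the same fixed order for every subject.
* **Absent** shows a blank white screen.

Orientation always keeps the head toward the experimental fish: yaw snaps
to 0° (head left) or 180° with ties unchanged, pitch is the elevation of
the target clamped to ±30°.

## The fish agent (the synthetic-data generator)

The experimental fish is an Ornstein–Uhlenbeck swimmer
(`agent_params()`): velocity relaxes at 2 s⁻¹ toward a 6 cm/s cruise along
its current heading, perturbed by Gaussian velocity noise
(4 cm·s⁻¹·s⁻¹ᐟ²), softly repelled within 2 cm of a wall, reflected at the
boundaries (clamping would make the walls sticky), and — the one social
ingredient — accelerated toward the midpoint of a monitor wall with a gain
κ that depends on the motion type currently displayed there. A stimulus
that has moved within the last second earns a 1.5× salience bonus;
invisible or absent stimuli pull with κ = 0. Head, body and tail keypoints
trail along the heading at 1-cm spacing (a 3-cm fish).

This agent is explicitly a stand-in, not a model of zebrafish cognition.
What it emulates: smooth, bounded, tank-filling trajectories at realistic
speeds whose spatial bias appears only while stimuli are displayed, with a
monotone link between the attraction gain and the measured preference.
What it does not emulate: learning within or across sessions, burst-glide
kinematics, thigmotaxis, habituation, or any operant mechanism — so
passing tests validate the *pipeline* (controllers, schedule, scoring,
statistics), never behavioral conclusions about fish.

The attraction map was calibrated once (`scripts/calibrate.R`) so that a
full simulated first experiment lands on the observed fold-preference
scale: κ(chasing) = 1.3 and κ(motionless) = 0.3 give pooled stimulus-period
geometric-mean preferences of roughly 14× (chasing vs absent), 7× (chasing
vs motionless) and 1.9× (motionless vs absent) — all within ±50% of the
observed 18.6 / 5.0 / 1.9 — while keeping the Period-1/3 baselines within
0.01 of zero. The cruise speed of 6 cm/s was fixed at the same time: slower
fish mix too slowly after stimulus offset and leak a spurious positive bias
into the post-stimulus baseline. With two free gains against three target
folds the middle condition cannot be matched exactly; the calibration is a
demonstration, not an acceptance gate, which would be circular. The
second-experiment gains (fleeing 0.55 < flipped 0.75 < independent 0.9 <
chasing 1.3) only encode the observed preference ranking qualitatively.

## The vision stand-in

The physical rig minimises false positives by running two detectors and
accepting body-part estimates only inside the object detector's bounding
box. The package keeps that *gating contract* but replaces the trained
networks with classical operators on synthetic frames: `render_frames()`
draws the fish as a dark ellipse with a darker head disk on a white 640 x
360 frame plus a depth raster; `detect_bbox()` thresholds and labels
connected components (largest component ≥ 30 px, box padded 2 px);
`detect_keypoints()` takes the blob's principal axis, reads the head as the
centroid of the dark head disk (frame-local and deterministic, rather than
disambiguating by motion direction) and the tail as the opposite axis end.
Imperfection is injected explicitly — Gaussian keypoint jitter and a
per-frame miss probability — and a miss carries the last valid state
forward flagged `valid = FALSE`, the minimal-motion hold (the published
account reports occasional false negatives but not its hold policy).

The end-to-end oracle runs one simulated minute twice: once with
controllers fed the true head ("direct"), once through
render → detect → gate → 3D conversion ("full stack"), with jitter and
miss off and social attraction κ = 0. With κ = 0 the fish trajectory is
identical in both runs by construction, so the per-frame stimulus
discrepancy isolates exactly the vision–controller chain; the acceptance
suite requires < 2 px per frame (measured ≈ 0.2 px). With κ > 0 the same
comparison would instead measure sensitive dependence of the behavioral
loop — a one-frame salience flip perturbs the fish path and grows without
bound — which is a property of chaos, not of tracking.

## Schedule

`build_experiment1_plan()` / `build_experiment2_plan()` reproduce the full
within-subject designs: eight subjects (4M/4F), each condition as eight
consecutive sessions with the two stimuli swapping monitors after the
fourth (4/4 side counterbalance), condition orders following the published
per-fish-group tables (the order literals live in one file,
`R/scheduler.R`, so any transcription question is isolated there). Each
20-min session is four 5-min periods — presession, 1, 2, 3 — with stimuli
displayed only in Period 2; the presession is simulated but excluded from
analysis, matching its acclimation role. The blank-monitor control
(Absent-vs-Absent) is interspersed as four two-session sets. In the first
experiment these sit before the first condition and after each of the three
conditions; the second experiment has four conditions but the same stated
total of eight control sessions, so the sets occupy the gaps — before the
first condition and after each of the first three. Per-session seeds are a
stable hash of (experiment, fish, session), so any single session is
reproducible in isolation; within a session all draws come from one R RNG
stream in a frozen order (left stimulus, right stimulus, agent), consumed
identically by the compiled and the reference R engine (tested for
bit-identity).

## Preference index

For each period, the per-frame head position (carried-forward frames count
at their last valid position) is scored into compartments at 1/30 s per
frame. Within a condition the times are **pooled across the eight sessions
before the ratio is taken**: `log10(ΣT_A / ΣT_B)`, with each session's
left/right assignment deciding which compartment counts toward A. This is
deliberately not the mean of per-session log ratios, and a regression test
guards the distinction. For the blank-monitor control the virtual rule
assigns A to the left compartment in the first session of each set and to
the right in the second. The log base is 10 — forced by the published pair
of a 0.70 mean log ratio with a 5.02 antilog (base e would give 2.01) — and
the antilog of an arithmetic mean log ratio is reported as the
fold-preference (geometric mean) scale. If a pooled side time is zero
(possible only for pathological agents) half a frame (1/60 s) is
substituted with a warning.

## Inferential chain

`run_paper_analysis()` runs the published chain on the long table of log
ratios (one row per fish x condition x period, treatment contrasts anchored
at Period 2 and the blank-monitor control):

1. **Random-structure selection** by AICc
   (`AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)`, implemented directly) over
   maximum-likelihood fits of the candidate set — by-fish intercept plus up
   to two simultaneous random slopes (Period, Condition); ties go to fewer
   parameters. Singular fits are tolerated during comparison rather than
   discarded.
2. **Final fit by REML** with Satterthwaite degrees of freedom (lmerTest);
   ML for comparisons, REML for reporting is standard practice, and the
   fractional dfs in the published coefficient tables indicate such an
   approximation without naming it — both flags are recorded in the output.
3. **Likelihood-ratio tests** of the fixed effects on ML refits
   (interaction, then each main effect), against the chi-square reference.
4. **Estimated marginal means** (emmeans, equal weights over the other
   factor) and the two post hoc families — between conditions within each
   period, between periods within each condition — with Holm–Bonferroni
   adjustment applied within each family (`stats::p.adjust` behind the
   package's operation surface, hand-checked in the tests).

One calibration caveat is worth stating plainly: at the study's own size
(8 subjects, 96 rows) the asymptotic chi-square LRT on the 6-df interaction
is anticonservative — the type-I rate in the package's null simulations is
near 0.10, not 0.05. The chain is implemented faithfully rather than
patched with a small-sample correction the original analysis did not use,
and the acceptance suite therefore calibrates the *implementation* at 16
subjects (n = 192), where the asymptotics hold (measured ≈ 0.05 over 1000
replicates). Power for a 0.7-log-unit Period-2 effect at 8 subjects, with
noise matched to the synthetic pipeline (per-fish SD ≈ 0.05, residual
≈ 0.06 measured from blank-monitor runs), is effectively 1.

## Problem sizes and numerical choices

The test and acceptance suites run full-length sessions (36,000 frames)
wherever the property concerns the study design: the null calibration and
the recovery grid use 8 fish x 8 sessions per cell (the compiled loop
simulates a 20-min session in ~15 ms), the demonstration run is the
complete first experiment (256 sessions), the vision oracle uses one
1800-frame minute (rendering dominates), and the LRT calibration uses 1000
replicates. Smaller frame counts appear only in unit tests of bookkeeping,
where any multiple of 4 scales all periods together.

Other numerical conventions: pixel (i, j) of a rendered frame is centered
at continuous coordinates (i − 0.5, j − 0.5); bounding-box edges are
inclusive for gating; stimulus positions are clamped to the screen while
projected targets are not; wall reflection repeats up to 8 times for
extreme steps; the pursuit step `min(d, d·dt·1000/650)` cannot overshoot;
fleeing's "left side of the monitor" is `u < width/2`, with the midline
counting as right.

## Known limitations

* The agent cannot validate behavioral mechanisms — only the measurement
  and inference pipeline around them.
* The vision stack is a stand-in: no occlusion, reflections at the glass,
  water-surface refraction, or multi-fish scenes; detector imperfection is
  a two-parameter caricature (jitter + dropout) of real detector error.
* The full-stack runner supports the pursuit-family programs
  (absent/motionless/chasing/flipped); fleeing and playback sessions run
  direct-state only.
* Published group-level statistics from live animals (coefficient tables,
  marginal means) are not reproduction targets: they depend on the animals
  themselves. The deposited long table can be ingested
  (`read_preference_table()`) to re-run the statistics stage on the
  original records.
* The asymptotic-LRT anticonservatism at n = 8 noted above applies equally
  to any reanalysis at the study's size.
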