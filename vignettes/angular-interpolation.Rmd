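---
title: "Angular-interpolation control of a hybrid prosthetic arm: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angular-interpolation control of a hybrid prosthetic arm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
kinematic model and its conventions, the goal-predictor networks and how
they are trained, the interpolation control law and its degenerate cases,
the synthetic movement generator that stands in for human recordings, the
metric suite, and — importantly — what the simulated results do and do not
say about the human-in-the-loop setting.

## 1. The hybrid arm and its kinematic model

A *hybrid arm* couples two proximal joints (shoulder flexion/extension
`sfe`, adduction/abduction `saa`) mirrored from the user with five distal
joints (`hr`, `efe`, `fps`, `wru`, `wfe`) driven by a controller. The
7-DoF chain in `forward_kinematics()` uses three intersecting shoulder
axes, one elbow axis, one forearm axis and two intersecting wrist axes —
the standard anthropomorphic decomposition, equivalent to a
Denavit–Hartenberg chain with ±90° twists between successive axes.

Conventions (all chosen here, since only the frame's location and
orientation are anatomically fixed):

* origin at the shoulder; +x rightward, +y upward, +z forward
  (trunk-aligned); the reference posture is the arm hanging along −y;
* angles in degrees throughout (the 1° latch and the 5–10° task tolerances
  are stated in degrees), positions in metres;
* flexion-type joints (`sfe`, `efe`, `wfe`) rotate about −x so positive
  flexion moves the limb forward; abduction moves the (right) arm toward
  +x; `hr` and `fps` rotate about the segment's long axis;
* the hand is modelled as a segment from the wrist to the
  middle-of-grasp point (`hand` length, default 8 cm); the *grasp axis* is
  the hand-segment direction. Its orientation is reported as the signed
  projection angles α (frontal plane, x–y) and β (sagittal plane, y–z),
  zero for a vertically hanging axis, in (−180°, 180°]. The map
  axis ↦ (α, β) is invertible except for exactly horizontal axes, a
  measure-zero set that sampled postures do not hit.

The elbow has no kinematic singularity in this representation, but near
full extension the hand position becomes insensitive to `efe`; target
generation therefore shrinks the elbow interval to 85% of its span about
its midpoint.

## 2. Goal predictors

Three feed-forward variants map the movement goal to a distal
configuration. All share one architecture — dense 256 (ReLU), dense 256
(ReLU), dropout 0.5 (training only, inverted scaling), dense 64 (ReLU),
linear output — and one schedule: stochastic gradient descent with
momentum, mean-squared-error loss on angles in degrees, 10 epochs, batch
size 128.

| variant | inputs | outputs | learning rate | momentum |
|---|---|---|---|---|
| PC− | x, y, z, α, β, sfe, saa | 5 distal | 1.59×10⁻⁷ | 0.95 |
| PC+ | x, y, z, α, β, sfe, saa | 5 distal | 10⁻⁴ | 0 |
| C+  | x, y, z, α, β | all 7 (5 used) | 10⁻⁴ | 0 |

Design choices where the published description is silent:

* **Optimizer.** Naming a learning rate and a momentum implies plain
  SGD-momentum; no adaptive optimizer is used.
* **Loss scale.** A learning rate is only meaningful jointly with the
  loss's summation convention (mean vs. sum over batch and output
  dimensions), which is not published. The package fixes the convention
  once with a global `grad_scale` (default 20, identical for all
  variants) in `network_spec()`: the loss gradient is that of the plain
  mean MSE multiplied by `grad_scale`, so the PC+ schedule
  (10⁻⁴ × 20 = an effective 2×10⁻³) reaches its loss plateau within the
  prescribed ten epochs on the reference synthetic database. A scan of
  effective rates (10⁻³…8×10⁻³) showed a plateau between 2×10⁻³ and
  4×10⁻³; the lower end was kept. Under this convention PC−'s published
  rate is, as expected, too small to train usefully — `network_spec()`
  accepts an `lr` override for practical PC− demonstration runs, and that
  override is used wherever a working direct control is needed.
* **Normalization.** Inputs are z-scored with statistics fitted on the
  training data and stored in the predictor; outputs stay in raw degrees
  (standardized outputs were tested and performed no better under any
  reduction convention).
* **Initialization.** Seeded Glorot-uniform; the training seed covers
  initialization, shuffling and dropout masks, so a seed plus data fully
  determines the predictor.
* **No early stopping, no validation split** — ten fixed epochs.

## 3. The interpolation law

`angular_update()` implements the per-tick law (the two algebraically
equivalent forms — gap over estimated movement time × frequency, and gap ×
locked-displacement over remaining distance — agree to 10⁻⁹ degrees when
the update rate equals the sampling rate; the distance-ratio form is the
canonical implementation because it is robust to timestamp jitter).
Degenerate cases, decided here:

* **Zero locked-hand motion** (`S_h = 0`): the distal joints hold. The
  law yields a zero update and the user stays in command; nothing moves
  unless the user moves.
* **Displacement exceeding the remaining distance**: the interpolation
  fraction is clipped to [0, 1] so a joint never overshoots its goal
  (configurable via `controller_config(clip = )`).
* **Latching is per joint**: each joint within 1° of its goal snaps to
  the prediction and tracks it *continuously* (the prediction keeps
  moving with the proximal inputs under PC+) until
  `reset_on_target_change()` clears the latches. The alternative — a
  latched joint frozen at the latch-time value — was rejected because it
  would leave the hand subtly misaligned while the user fine-positions.
* **Target changes preserve state**: the distal angles, hand position and
  time survive a reset; only the latches clear. This continuity is the
  entire point of the method, and the test suite asserts the contrast
  with direct control (full prediction-gap jump in one 11 ms tick).
* **Remaining distance** uses the true hand position (including the
  distal contribution), while **speed** uses locked positions only; the
  asymmetry is deliberate — speed must be insensitive to the controller's
  own output, distance must be real.

## 4. The synthetic movement generator

Every human-derived input of the original experiments is emulated in
`synthetic.R` so the stack is testable end to end:

* **Movement database**: 12 synthetic "participants", each with
  independently jittered (±5°) ranges of motion, performing chained
  minimum-jerk joint-space movements (profile 10τ³ − 15τ⁴ + 6τ⁵, zero
  end-point velocity and acceleration) between postures sampled inside
  the (elbow-scaled) ROM, durations uniform 1–2 s at 90 Hz. Defaults:
  400 movements ≈ 5.4×10⁴ frames. Each trial starts from the previous
  trial's end posture, mirroring pick/place alternation.
* **Training sets** retarget database angles onto the user's segment
  lengths and compute, per frame, the pose of a hypothetical target held
  in the hand — so every sample is kinematically self-consistent by
  construction.
* **Target sets**: *plausible* targets are contexts of postures drawn
  uniformly within the ROM (elbow 85%); *possible* targets are drawn from
  actually performed trajectories; `rom_from_database()` implements the
  variant that combines a user's shoulder limits with the 5–95% distal
  quantiles of a database.
* **Simulated user**: a minimum-jerk (or constant-speed, optionally
  noisy) shoulder reach toward the target's generating proximal posture,
  followed by *hunting* — observation-driven hill climbing in the 2-D
  shoulder space (keep the direction that reduced the observed pose
  error, redraw it otherwise; default step 0.9°/tick). This mirrors what
  participants visibly do: wiggle the shoulder until the object
  validates. A configurable reaction delay models the latency of the
  validation button press (default 0 s, so validation time is 0 by
  construction — it is a human quantity, exposed as a parameter, not
  predicted).

What the generator does **not** emulate: human motor synergies. Real arm
movements occupy a low-dimensional manifold of coordinated joint
combinations; uniform-in-ROM posture sampling spreads the same number of
samples over a much larger input region. Consequences below.

## 5. Metrics

* **SR, MT, VT** as defined for the task (VT from the *last* entry into
  the validation zone). Trajectory metrics are computed on successful
  trials only, medians per phase.
* **Spectral arc length**: original parameterization — speed profile from
  hand positions, FFT with zero-padding factor 4, magnitude spectrum
  normalized by its zero-frequency value, frequency axis normalized by a
  20 Hz cutoff, negative arc length of that curve; the spectrum is
  interpolated onto the exact cutoff so the bound SAL ≤ −1 holds
  structurally. The later adaptive-cutoff variant of this metric exists;
  the original fixed-cutoff form is used and frozen in the tests.
* **Curvature**: maximum distance from the chord between the endpoints;
  **distance index**: path length over chord length (≥ 1).
* **Shoulder spread volume**: covariance ellipsoid scaled to the 97%
  χ²₃ quantile, volume (4/3)π√det(Σ)·q^{3/2}, reported in dm³. In this
  simulator the shoulder itself is a fixed origin, so SV is exercised on
  synthetic clouds in the tests rather than on simulated phases.
* **Offline distances**: trajectories reconstructed by replaying recorded
  shoulder motion through a control; MMAE is the median over frames of
  the mean absolute joint error (proximal pair and distal five
  separately; per-trial values are medianed across trials), MHPD the
  median hand-position distance, MHOD the median angle between grasp axes
  (spin-free, cylindrical object).

## 6. Problem sizes and determinism

Reference experiment sizes, chosen once: 400 movements (≈ 5.4×10⁴
training frames), 200 held-out targets for goal-recovery, 100-target
phases at the 3 cm / 10° / 6 s constraints, 10⁴ random states for the
controller-law identity, 10³ postures for the kinematics oracle. Every
stochastic step takes an explicit seed and restores the caller's RNG
state; phase runs derive per-trial seeds from the phase seed.

## 7. Known limitations, and what the synthetic results mean

* **Goal-recovery accuracy is data-limited, not optimization-limited.**
  On ~5×10⁴ synthetic samples the PC+ predictor reaches a median held-out
  goal-pose error of roughly 4–5 cm and 15–19° (axis) on uniform
  ROM-sampled targets. Diagnostics in the development history: label
  consistency at near-identical contexts is ~1°, so the inverse map is
  well-posed on this data; a 1-nearest-neighbour regressor is *worse*
  (≈10 cm / 27°), and quadrupling the database improves the network while
  quadrupling the epochs does not — the (context, proximal) input
  manifold is six-dimensional, and 5×10⁴ samples are ~5 points per
  dimension. Human movement databases are far more favourable: natural
  coordination concentrates both the training data and the queries on a
  low-dimensional synergy manifold.
* **Closed-loop success rates in this simulator are therefore well below
  the >92% achieved by human participants.** With the hunting user the
  interpolation control validates roughly half of the 3 cm / 10° targets
  within 6 s; a multistart search over the entire shoulder space shows
  that, for the remainder, *no* proximal configuration brings this
  predictor's goal pose inside both tolerances — the bottleneck is
  predictor accuracy, not the control law or the user model. The
  control-law properties themselves (formulation equivalence, linear gap
  decay, zero-motion hold, latch semantics, discontinuity erasure) are
  exact and hold at machine precision in the tests.
* **The natural-replay control is the gold standard** and validates 100%
  of its own generating targets, which pins the task geometry, the
  validation zones and the trial machinery.
* No grasping, no torque or velocity limits beyond ROM saturation, no
  biomechanical dynamics, no questionnaires, no group statistics.
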