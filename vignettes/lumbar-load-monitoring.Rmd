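---
title: "Estimating lumbar moments from wearable sensors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lumbar moments from wearable sensors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Overexertion injuries of the low back accumulate with repetitive lumbar
loading during manual material handling. The loading metric of interest is
the time-series net internal moment at the L5/S1 joint — the extension
moment resisting forward flexion, and secondarily the frontal-plane lateral
bending moment. In a motion laboratory these moments are computed by
bottom-up inverse dynamics from optical kinematics and force-plate ground
reaction forces (GRFs); outside the laboratory they must be estimated from
body-worn sensors. This package implements, end to end, a tested pipeline
for studying that estimation problem: a synthetic data generator that
emulates an instrumented lifting study with exact ground truth, wearable
channel construction (idealized and realistically degraded), per-sample
gradient-boosted regression under leave-one-subject-out cross-validation
(LOSO CV), an exhaustive sensor-location ablation, and the accuracy and
importance metrics used to compare sensor combinations.

## The synthetic study

Because the raw laboratory data the problem is defined on are not public,
the package generates a cohort that emulates the described study
conditions: 10 participants (height 1.8 ± 0.1 m, mass 79 ± 14 kg, truncated
normal), each performing about 400 pick-and-place tasks with boxes of
0–23 kg moved between shelves at three heights (0.30, 1.00, 1.50 m) in four
movement styles (squat, stoop, lateral, diagonal). The default battery
factorization is 5 masses × 5 shelf pairs × 4 styles × 4 repetitions = 400
tasks; one repetition gives the 100-task battery used in the packaged
evaluations. Mass 0 (a bend with nothing in the hands) is deliberately
included: distinguishing a loaded lift from an empty-handed bend is exactly
what a posture-only sensor cannot do.

### Body model

Eight rigid segments — two feet, shanks, and thighs, a pelvis, and a trunk
with head and arms lumped in — plus the handheld box as a point mass at the
hand point. Segment masses, lengths, centre-of-mass positions and radii of
gyration are dimensionless fractions of body mass and height in the style
of the classical anthropometric proportion tables, stored as data
(`default_segment_params()`) and overridable. Mass fractions sum to exactly
1 by construction. Arms are not articulated: the hand point is placed by an
arm-reach vector from the shoulder, which suffices for an L5/S1 target
(the object's wrench is what matters, not arm inertia). The global frame is
X anterior, Y up, Z to the participant's right; extension is the +Z
component of the internal moment on the trunk at L5/S1 and lateral bending
the +X component.

### Trial synthesis

Each trial is built from five keyframe postures: upright, reach to the
origin shelf, an upright-ish carry, reach to the destination shelf, and
upright. A planar posture solver finds each reach keyframe: a style
template (knee-dominant for squat, trunk-dominant for stoop, with axial
rotation and lateral lean added for lateral/diagonal tasks) is scaled by a
bend depth solved so the hand meets the shelf height, with the arms
carrying a style-dependent share of the reach; a balance correction then
tilts the chain about the ankles so the static whole-body centre of mass
sits over the feet. Keyframes are interpolated with minimum-jerk time
scaling (quintic; zero velocity and acceleration at keyframes) and all
velocities and accelerations are obtained by analytic differentiation of
the interpolant — no finite differences anywhere in the ground-truth path.

Inter-trial variability is part of the data model, not an afterthought:
joint-angle templates vary by about 12% between repetitions (matching the
5–15° trial-to-trial variability lifters exhibit), the arm-versus-bend
share of each reach varies, each keyframe's balance point wanders a few
centimetres (postural sway), task durations jitter by ±10%, and every
participant carries a persistent stoop-versus-squat preference. Without
this variability the insole centre of pressure becomes an unrealistically
clean encoder of posture — a deterministic simulator artifact — and the
relative value of sensor locations is distorted.

The handheld load transfers on a linear 0.1 s ramp at pick and place to
avoid force discontinuities. Double support is assumed throughout; tasks
that would require stepping are outside the battery.

### Ground reaction forces and ground truth

Per-foot GRFs are synthesized, not simulated independently: the whole-body
inertial-plus-gravity wrench (including segment angular momentum rates) is
computed from the kinematics, split between the feet by a frontal-plane
lever rule on the combined centre of mass (clipped to [0, 1]), and each
foot's centre of pressure is solved on the ground plane about its own foot
reference. When fast transfers push the CoP beyond the sole — which real
lifters produce and real insoles saturate at — the CoP is clipped to the
support polygon and the remainder is carried as a free-moment couple, so
whole-body closure is never violated. Ground truth lumbar moments come
from bottom-up recursive Newton–Euler (foot → shank → thigh → pelvis →
L5/S1); an independent top-down recursion (trunk + object about L5/S1) is
kept as an oracle, and on every noise-free trial the two agree to better
than 1e-9 relative RMS — this closure is the package's central correctness
check. Moments are reported in units of body weight × body height
(BW × BH); the Newton-metre conversions use cohort-mean mass and height.

## Wearable channel sets

The *idealized* set (51 channels) represents what wearables could report if
signal quality were not a limitation: 8 segments × 3 Euler angles (Z–X–Y,
sagittal first; declared, since only the "XYZ" naming is conventional),
7 joints × 3 angles, and per-foot insole channels — the 3D GRF projected
onto the sole normal, and the CoP transformed into the foot's planar frame
(X toe-ward, lateral coordinate named `cop_y` per insole convention).
Negative projected forces are floored at zero, with the count recorded: an
insole cannot pull on the foot.

The *real-emulated* set (179 channels) mirrors a commercial IMU suit
export: 11 segments (pelvis, L5, L3, T12, T8, bilateral thighs, shanks,
feet) × {3 Euler + 4 quaternion + 3 angular velocity + 3 linear
acceleration} + 10 joints × 3 + the 6 insole channels. L5, L3 and T12 are
model-based spine segments emulated by spherical interpolation between
pelvis and trunk orientations at fractions 0.2/0.45/0.7; T8 carries the
trunk-mounted IMU itself (fraction 1.0). That last choice matters for
subsetting: a channel is available to a sensor subset only if every sensor
it requires is worn, and tying T8 to the trunk sensor alone keeps the
trunk-only configuration meaningful, while the interpolated spine segments
require pelvis + trunk. The same conservative rule assigns each joint
angle to the pair of adjacent segment IMUs.

Sensor degradation (`degrade_to_real()`) perturbs exactly what physical
sensors get wrong, and nothing else: a per-trial multiplicative gain error
(default sd 0.08) and additive white noise (10 N) on insole forces, 5 mm
CoP noise, and per-trial orientation bias (1°) plus white angular noise
(0.5°) on each IMU. These magnitudes are declared defaults — the emulated
study describes insole force variability qualitatively but does not
quantify it — chosen so that insole degradation dominates, and all are
configurable. Ground truth is never touched. When features are built from
a degraded trial, orientation channels are low-pass filtered at 6 Hz and
force/CoP channels at 10 Hz (3rd-order zero-lag Butterworth), mirroring
laboratory practice; analytic noise-free trials bypass the filters, which
is why a zero-noise degradation reproduces idealized channels exactly.

## Estimator and validation

The estimator is per-sample: signals at one time sample predict the moment
at that same sample, with no temporal context. Models are gradient-boosted
regression trees with histogram binning (100 trees, learning rate 0.1,
255 bins, 31 leaves, minimum 20 samples per leaf, squared-error loss),
provided by xgboost's `hist` method behind the package's fit/predict
surface; fits are deterministic given the configuration and seed, and no
hyperparameter search is performed (the defaults are documented and
fixed — an ensemble of ~100 trees is the stated design point).

Before modeling, insole channels receive a per-wearer calibration
(`calibrate_insoles()`): each participant's normal-force channels are
divided by their session mean — a body-weight-scale gain calibration — and
CoP channels are re-centred on their session mean — a stance-origin
calibration. The rationale is mechanistic: a per-sample tree model cannot
separate body weight from box load in a raw newton-scale force for a
person it has never seen, so raw forces do not transfer across subjects of
different mass; every deployed insole system calibrates to its wearer for
exactly this reason (and supplementing or calibrating a wearable per
worker is a natural part of such a workflow). The calibration uses input
signals only — no targets, no other participants — so it cannot leak
across cross-validation folds. Orientation and joint-angle channels need
no such step; angles are already comparable across people.

Validation is leave-one-subject-out: for each fold the per-channel z-score
normalizer and the model are fit on nine participants and evaluated on the
tenth, so every sample is predicted exactly once by a model that never saw
that participant, and the normalizer is refit per fold (the leakage-safe
reading of "normalized during development"). Accuracy is summarized by
r² = 1 − SS_res/SS_tot per participant (not squared Pearson correlation —
the definition is recorded and switchable in principle, but 1 − SS_res/SS_tot
is what the package computes), RMSE in BW × BH with a Newton-metre
conversion, and MAPE restricted to samples whose true moment exceeds
0.05 BW × BH, since percent error is unstable near zero. Channel
importance is permutation importance: the drop in held-out r² when one
channel is shuffled within each held-out participant, averaged over 5
repeats and all folds. A documented non-property: per-channel Δr² values
do not sum to the baseline r², and a signal highly correlated with another
input can look unimportant while being individually predictive — the
package's test suite demonstrates both.

The sensor ablation enumerates all 62 subsets of 1–5 of the six candidate
locations (trunk, pelvis, thigh, shank, foot, insole; bilateral locations
always as pairs) plus the full distributed set, runs the complete
normalize → LOSO → evaluate pipeline per subset, and flags the best subset
per size (ties broken by fewer channels, then name). Failed subsets are
recorded with diagnostics without aborting the sweep, and a fixed master
seed reproduces every metric exactly.

## Problem sizes in the packaged evaluations

The packaged evaluation scripts use sizes chosen to exercise the study
conditions while remaining comfortable on a single CPU: the headline
comparisons (trunk, insoles, trunk + insoles, distributed) run on the full
10-participant × 100-task battery; the 63-subset sweep, whose asserted
property (best-per-size accuracy non-decreasing in subset size) is
scale-free, runs on a 6-participant × 24-task cohort; the noise-sensitivity
comparison uses 6 participants × 24 tasks with the real-emulated channel
set. Feature tables keep every 4th 100 Hz sample (25 Hz effective): the
estimator is per-sample and the kinematics are 6 Hz band-limited, so this
discards only redundant rows.

## Numerical choices and degenerate inputs

- Zero-lag filtering wraps `signal::filter` with odd-reflection padding and
  steady-state initial conditions; constants pass through to 1e-14 and the
  two-pass magnitude response is the squared Butterworth. Edge transients
  decay within roughly half a second of the series ends.
- Resampling is anti-alias filtering (when downsampling) plus cubic spline
  interpolation on the dense grid; `signal::resample`'s uncompensated
  polyphase delay made it unsuitable.
- Quaternions are stored w-x-y-z, kept sign-continuous along a trial, and
  renormalized after degradation; Euler extraction clamps the gimbal
  argument.
- Constant channels are flagged by the normalizer and passed through
  unscaled; an all-constant channel provably changes no tree prediction.
- Degenerate metric inputs (zero-variance targets, empty inputs, no samples
  above the MAPE threshold, all-zero paired differences in the signed-rank
  test) raise errors rather than returning numbers.
- The estimator emits float32 predictions; "exact" fits are exact to single
  precision (~1e-7), and tests assert accordingly.

## What passing tests do and do not show

The generator produces dynamically consistent, variability-rich trials with
exact ground truth, which is precisely what makes the pipeline testable:
closure to 1e-9, exact static limits, and deterministic reproduction. It
does not reproduce soft-tissue artifact, marker dropout, stepping,
asymmetric load sharing between hands, or true neuromuscular control, and
its noise model is a declared stand-in. Consequently, accuracy numbers on
synthetic data characterize the pipeline, not any real sensor product:
the package asserts orderings and trends (insoles add accuracy to a trunk
IMU for every participant; best-per-size accuracy grows with sensor count;
posture-only sensors miss load magnitude; insole noise erodes the insole
benefit and removing it restores the benefit), not the real-world r²
values, which are attainable only with the laboratory data the emulation
stands in for.

One consequence of the simulator's design deserves emphasis: with double
support, symmetric stance, no stepping, and an all-pick-and-place battery,
the total insole force and CoP profiles are more tightly coupled to the
lumbar moment than they are in real warehouse-style data, where walking
between shelves and asymmetric stances break that coupling. After
per-wearer calibration, an insole-only model on synthetic data therefore
performs better, relative to a trunk-only model, than an insole-only model
does on real data. Orderings involving the insole-only configuration
should be read with that in mind.

## Known limitations

Kinematics are keyframe-scripted rather than optimal-control derived, so
velocity profiles are smoother than human lifting; the lateral/diagonal
reach geometry is approximate (the object follows the hand point, shelves
are not collision-checked); the free-moment couple absorbs CoP clipping
rather than re-planning balance; and the spine-segment emulation is an
orientation interpolation, not a vertebral model. Each is acceptable for
the package's purpose — studying sensor-fusion estimators against exact
ground truth — and each is the first thing to revisit if the generator
were pointed at a new scientific question.
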