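---
title: "From raw dual-IMU signals to joint angles and gait events: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw dual-IMU signals to joint angles and gait events: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbkin)
```

## The measurement problem

Compression therapy for lower-limb lymphedema prescribes daily exercise —
maximal flexion-extension of the knee and ankle, and walking — whose effect
and adherence are hard to quantify outside the clinic. A two-unit inertial
wearable worn across the joint (one 6-DoF IMU on the proximal segment, one
on the distal segment, both read synchronously by a single
microcontroller at 52 Hz) can measure the sagittal joint angle, the range
of motion (ROM) of each exercise repetition, and the temporal structure of
gait. `limbkin` implements the full processing chain for such a device and
the statistics needed to validate it against a gold standard, plus a
ground-truth simulator so that every stage is testable without hardware.

No magnetometer is used anywhere: the intended environments (treadmills,
indoor clinics) are magnetically hostile, so the device carries
accelerometer and gyroscope only, and yaw is observable only through gyro
integration. All of the kinematics of interest live in the sagittal plane,
which the pitch angle captures without any need for absolute heading.

## Sensor model and calibration

Accelerometer readings are in g with an 8 g full scale; gyroscope readings
in deg/s with a 1000 deg/s full scale. Two deterministic error terms are
corrected before fusion:

* **Gyro bias** — the time average of a static stream
  (`estimate_gyro_bias()`). A motion check (per-axis gyro SD below
  2 deg/s by default) guards against accidentally averaging a moving
  stream; 2 deg/s is far above electronic noise on a resting surface and
  far below any voluntary limb motion.
* **Accelerometer offset and per-axis scale** — from six static
  placements, one per face-up/face-down orientation of each axis
  (`estimate_accel_calibration()`). With `m+` and `m-` the mean readings
  of the ±1 g placements of axis *k*, the minimal model identifiable from
  this protocol is `offset_k = (m+ + m-)/2`, `scale_k = (m+ - m-)/2`, which
  maps the two placements to exactly ±1 g. Cross-axis misalignment is not
  identifiable from six static placements and is deliberately not modeled;
  neither is gyroscope scale (that would need a rotation rig).

`apply_calibration()` applies `gyro - bias` and `(accel - offset)/scale`
per sample and is exactly invertible given the parameters.

## Orientation fusion

Each unit's orientation is a unit quaternion estimated by a
gradient-descent complementary filter (the Madgwick IMU variant), written
from first principles in `madgwick_update()`: the quaternion rate from the
gyroscope is corrected along the normalized gradient of the objective that
aligns the predicted gravity direction with the measured accelerometer
*direction* (magnitude is discarded, so the update is invariant to a
positive rescaling of the accelerometer vector; a zero accelerometer skips
the correction entirely). The quaternion is renormalized after every step,
which keeps the norm within 1e-6 of unity over arbitrarily long runs.

Tunable parameters:

* `beta` (dimensionless, default **0.1**) — the gain weighting the gravity
  correction against gyro propagation. The publication describing the
  original algorithm reports the IMU-only optimum in the 0.03–0.1 region;
  0.1 favors fast convergence for exercise bouts of tens of seconds.
  `beta = 0` reduces the filter to pure gyro integration (used as the
  gyro-path oracle in the tests). Note that with a fixed `beta`, the
  static error floor is about `beta * dt` radians per step, ~0.1 degrees
  at 52 Hz — well under the bench accuracy of interest.
* `init_window_s` (default **0.5 s**) — the initial quaternion is the
  tilt (yaw = 0) implied by the mean accelerometer vector over this
  window, rather than the identity. The exercise protocols start from
  rest, so this removes the convergence transient that would otherwise
  bleed into the first repetition's ROM.

Euler angles use the intrinsic Z–Y′–X″ (aerospace) sequence with pitch
about the mediolateral y axis. The mounting convention is: y axis
mediolateral, x axis along the segment, so "pitch" *is* the sagittal-plane
rotation. At gimbal lock (|pitch| = 90°) roll is reported as 0 and yaw
absorbs the free rotation; walking and flexion-extension stay far from
this configuration. Time steps come from the logged timestamps, not the
nominal rate, for robustness to acquisition jitter.

## Joint angle and ROM

With that mounting convention, joint flexion drives both pitches positive
and the sagittal joint angle is the algebraic sum
`pitch_proximal + pitch_distal` (`joint_angle()`; a `distal_flip` switch
covers the opposite distal polarity). Flexion-extension repetitions are
segmented on the 4 Hz low-pass-filtered angle trace
(`segment_flexion_extension()`): prominent maxima (topographic prominence
at least `min_rom`, default 10°) are cycle peaks, the minima between
adjacent peaks are cycle boundaries, and a cycle's ROM is its peak height
above the mean of its two delimiting minima — a baseline choice robust to
slow drift between repetitions. Cycles shorter than `min_period_s`
(default 0.5 s) are rejected. Plateaued peaks resolve to their earliest
sample. The 4 Hz cutoff sits well above voluntary flexion-extension
(< 2 Hz) while stripping fusion jitter; the filter is a second-order
zero-phase Butterworth with odd-reflection edge padding, so event times
are not shifted and ROM is invariant (to floating point) to constant
angle offsets.

`rom_summary()` reports max ROM, mean ROM and the cycle count; an empty
cycle set yields an explicit empty summary rather than zeros, so "no
qualifying movement" is distinguishable from "zero-amplitude movement".

## Gait events

During walking, the pitch of the unit on the dorsum of the foot shows one
prominent swing peak per gait cycle of that foot. `detect_steps()` counts
those peaks on the filtered trace with a prominence gate (default 10°)
and a minimum separation of `1/max_cadence_hz` (default 3 Hz — generous
for 3–5 km/h walking at ~0.8–1.3 cycles/s per foot). "Step count" is the
number of cycles of the instrumented foot. Step time is the interval
between consecutive peaks.

Toe-off has no universally agreed single-trace criterion, so the rule is
configuration, not a claim: the default (`rule = "min"`) places toe-off at
the minimum of the filtered pitch in the window between the previous peak
and the current one — the foot is maximally plantarflexed as it leaves
the ground — and `rule = "gyro_zero"` instead takes the last
negative-to-positive zero crossing of the filtered pitch rate before the
swing peak. On smooth traces the two nearly coincide.

## The simulator: what it emulates and what it does not

`simulate_motion()` generates two-segment hinge motion with exact
analytic sensor signals: each segment's orientation is a pure pitch
rotation θ(t), the ideal gyro is (0, θ̇, 0) and the ideal accelerometer is
the gravity direction (−sin θ, 0, cos θ) in the segment frame. Scenarios:

* `static` — rest at a configurable pitch (`static_pitch_deg`).
* `flexion_extension` — raised-cosine joint-angle repetitions
  `A/2 (1 − cos 2πft)` (default A = 60°, f = 0.5 Hz, 4 repetitions,
  matching the exercise protocol's repetition count), split between
  segments (`distal_share`: 0.5 for the knee, 0.8 for the ankle — the
  shank carries most ankle motion).
* `walk` — a periodic foot-pitch template
  `sin 2πu − 0.25 cos 4πu` per cycle (u = cadence·t mod 1), scaled so the
  swing peak reaches `walk_foot_amplitude` (default 25°), with a small
  counter-phase 5° shank oscillation on the proximal unit. The template
  has exactly one sharp swing peak (second derivative −8π² at u = 0.25)
  and one *flat* quartic minimum (second derivative 0 at u = 0.75): the
  swing reversal is quick while the foot dwells plantarflexed around
  toe-off. That asymmetry is deliberate — it is what makes toe-off
  localization inherently noisier than swing-peak localization, the
  qualitative behavior seen in real gait data. Cadence presets are
  0.93 Hz (3 km/h) and 1.25 Hz (5 km/h) — engineering presets for typical
  treadmill walking, not measured cohort values.

Every motion scenario begins with a rest lead-in (`lead_in_s`, default
1 s): subjects start each protocol at rest, and the fusion initialization
window assumes as much. Noise is zero-mean Gaussian per axis
(`gyro_noise_sd`, `accel_noise_sd`); injected bias/offset/scale errors
are applied after the noise, exactly where a real sensor's deterministic
errors sit, and signals are clipped at the sensor full scale. All
randomness flows through one seeded generator and the caller's RNG state
is restored, so identical configurations with identical seeds are
bit-identical.

What the simulator does **not** model: linear acceleration of the sensor
during motion is off by default (the gravity-direction correction of the
filter assumes a gravity-dominated accelerometer; a `linear_accel` switch
adds the analytic centripetal/tangential term of a sensor mounted
`seg_length_m` from the hinge for stress testing), soft-tissue artifact,
bandage pressure, out-of-sagittal motion, and subject-specific gait
variability. Passing tests therefore demonstrate the correctness of the
*processing chain* under its stated assumptions, not device accuracy on
human subjects — that requires a physical gold-standard comparison, which
is exactly what the `agreement_stats` module is for.

## Agreement statistics

`linear_agreement()` fits device on gold by OLS and reports slope,
intercept and r² (squared correlation). `bland_altman()` uses
gold-minus-device differences (the orientation the validation literature
for this device family reports), the sample (n−1) SD, and the
conventional 1.96 multiplier for the limits of agreement.
`percentage_error()` is `100·|device − gold|/|gold|` per pair, with pairs
at `|gold| ≤ epsilon` (default 1e-6) excluded and counted — the ratio is
undefined at zero. Absolute error in degrees (the Bland-Altman bias) and
relative error in percent are distinct statistics and are never
conflated.

`compare_conditions()` gates on Shapiro–Wilk normality at 0.05 in *both*
samples: if both pass, a two-sided unpaired Welch t-test (the
unequal-variance default is the safer choice); otherwise the Mann–Whitney
rank-sum test. A constant sample, on which Shapiro–Wilk is undefined, is
treated as failing normality. Significance is `p < 0.05`; a `paired`
switch covers within-limb designs (bare vs banded on the same limb).

## Numerical choices and degenerate inputs

* Angles are degrees at every public boundary; radians only inside the
  quaternion math.
* Resampling (`resample_series()`, for pairing a 52 Hz device trace with
  a 100 Hz optoelectronic reference) is linear interpolation on a uniform
  grid within the input span — deterministic, order-preserving, and exact
  on linear signals; no extrapolation.
* Peak detection uses topographic prominence (height above the highest
  saddle toward a higher peak), not raw height, so slow baseline drift
  does not create or destroy events; conflicts within the minimum
  separation keep the more prominent peak.
* Empty inputs are explicit: empty recordings round-trip as header-only
  files; `rom_summary()` has an empty sentinel; flat traces yield zero
  steps, not errors. Integrity violations (non-monotone timestamps,
  mismatched stream lengths, missing CSV columns) fail fast with the
  offending row or column named.

## Problem sizes in the shipped tests

The test suite and the acceptance script run the full chain on simulated
recordings of 8–23 s at 52 Hz (hundreds to ~1200 samples), one 10-minute
walk (~31 000 samples) for the quaternion-norm soak, 50 seeded short
walks for the event-dispersion comparison, 100 random arrays for the
statistics oracles, and 2000 null replicates for the empirical size of
the gated test — sizes chosen so the whole suite completes in well under
a minute while every property is exercised at meaningful scale.
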