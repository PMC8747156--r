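---
title: "Perturbed-stance balance assessment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbed-stance balance assessment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbalance)
```

## Overview

`perturbalance` implements a benchmarking workflow for standing balance of a
human subject, with or without a lower-limb exoskeleton, under manually
delivered push perturbations. A hand-held instrumented perturbator measures
the 3-axis contact force and its own orientation; a pressure-sensing garment
(30 sensors grouped into eight body zones) localizes where the push lands and
carries a second IMU giving the body orientation. Four controlled variables
of each push — magnitude, duration, orientation, and location — are checked
against tolerance bands, and only compliant pushes count toward the protocol.
Balance outcomes are computed from joint angles via a planar link-segment
centre-of-mass (CoM) model.

This vignette documents the model and its assumptions, the tunable
parameters, the synthetic-data generator used for verification, and the
numerical choices that matter.

## The centre-of-mass model

The body is a five-segment rigid chain: bilateral shanks, bilateral thighs,
and a single head-arms-trunk (HAT) segment, with pure rotary joints and the
feet flat on the ground (the ankle is treated as fixed to the floor). Left
and right legs are assumed identical and symmetrically placed, so joint
angles are left/right averages and legs enter the mass weighting twice.

Two planar projections are used:

* **Sagittal (antero-posterior, AP)** — driven by ankle, knee and hip
  flexion/extension. Joint angles are relative rotations accumulated from the
  ankle: the shank is tilted `q_ankle` from vertical, the thigh
  `q_ankle + q_knee`, the HAT `q_ankle + q_knee + q_hip`. Positive angles
  lean segments forward.
* **Frontal (mediolateral, ML)** — driven by hip add/abduction only: the legs
  stand as a vertical column and the HAT rotates about the mid-hip point.
  This is the minimal frontal kinematic consistent with using a single
  add/abduction angle; it ignores pelvic obliquity and ankle in/eversion.

The coordinate frame is x forward, y up, z toward the subject's right. With
these conventions pushes from the front or from the right side drive the CoM
to negative sway angles, and an upright posture gives exactly zero sway.

Segment masses and CoM locations come from the classic Winter/Dempster
anthropometric fractions. Because the ankle is welded to the ground, the foot
mass (0.0145 of body mass per side) is folded into the shank, giving per-side
fractions shank 0.0610 and thigh 0.100; the HAT takes the remainder (0.678),
so the segment masses always sum exactly to the body mass. CoM positions sit
at 0.433 of segment length from the proximal end for shank and thigh and
0.626 for the HAT. All fractions are arguments of
`derive_segment_parameters()` and can be overridden, since published tables
differ slightly and the HAT length convention (hip to vertex vs hip to
shoulder) varies between studies; the default treats `hat_length` as the
distance from the hip to the top of the modelled HAT segment, whatever
landmark the user measured, because only the product
`com_fraction * hat_length` enters the model.

An exoskeleton is modelled as links of exactly the human segment lengths
(joints perfectly aligned), with link masses specified as fractions of the
exoskeleton mass and link CoMs at a configurable fraction of each segment
(default 0.5). The combined CoM is the mass-weighted average
`CoM_T = (CoM_H M_H + CoM_E M_E) / (M_H + M_E)`; when no exoskeleton is
present the human trajectory is returned unchanged, bit for bit.

The body sway angle per plane is the inclination of the ankle-to-CoM line
from vertical, `q_sway = atan(horizontal / vertical)`, reported in degrees.

## Controlled variables and the protocol

The protocol (`build_protocol()`) has sixteen conditions: eight location
zones (mid/upper back, mid/upper front torso, right/left side torso,
right/left shoulder) crossed with two magnitude levels, in a fixed order.
Five valid repetitions per condition are required before the session
advances; rejected pushes are logged and never counted.

Tolerances (`default_tolerances()`, all overridable):

| Controlled variable | Band | Notes |
|---|---|---|
| magnitude | 8 ± 2 % (Low), 16 ± 2 % (High) of total mass | converted to newtons as `pct/100 × M × g`, g = 9.81 m/s², M = body + exoskeleton mass |
| duration | 0.35 ± 0.15 s | time the resultant force exceeds 5 N, measured on the 30 Hz grid (±1 sample quantization) |
| orientation | ±30° in pitch and yaw | about the zone's perpendicular: yaw 0° for back zones, 180° front, +90° right, −90° left; roll recorded, not constrained |
| location | ≥ 1 active sensor in the target zone | sensor active when its level exceeds its calibrated threshold |

Design notes:

* The magnitude bands are stated as a percentage of *mass* but the controlled
  variable is a force, so the band passes through g. Reading the percentage
  as kilograms-force instead changes only labels, not behaviour.
* Tolerance bands are closed; boundary values are accepted (the bands are
  stated as centre ± half-width), with a 1e-9 guard so grid-exact boundary
  durations are not lost to floating point.
* The Euler sequence for relative orientation is intrinsic Z-Y-X
  (yaw-pitch-roll), the AHRS convention of the IMU family used, and the
  relative rotation is `q_garment⁻¹ ⊗ q_perturbator`. Event-level
  orientation is the circular mean over the event's supra-threshold samples,
  so front-zone yaws near ±180° average correctly. Per-sample checking is
  available by validating individual samples, but the event mean is what the
  validator uses.
* Streams are paired by nearest timestamp with a configurable maximum skew
  (default one 30 Hz sample).

## Event detection and impulse

An event is a maximal run of samples whose resultant force magnitude exceeds
5 N. Duration runs from the first to the last supra-threshold sample; at
30 Hz this quantizes durations by up to one sample per edge, which is why a
smooth (raised-cosine) push planned with a given supra-threshold time is
recovered within two samples, while an idealized rectangular pulse aligned
to the grid is recovered within one.

The impulse integrates the resultant magnitude by the trapezoid rule,
extended from the supra-threshold run down the onset and offset ramps to
their local minima. The strictly-supra-threshold trapezoid systematically
loses the sub-5 N tails of a smooth push (1.5–8 % for realistic peaks at
30 Hz); following the ramps recovers the full-pulse integral to a few tenths
of a percent while adding nothing on a quiet baseline.

## Balance indicators

* **Body sway** is the signed sway-angle excursion of largest magnitude
  within the response window, measured relative to the pre-onset baseline
  (mean sway over the 0.5 s before onset) — subjects recover their initial
  stance between pushes, which need not be exactly zero sway. An
  absolute-zero reference is available (`baseline = "zero"`). The response
  window runs from onset to 3 s (the minimum spacing between pushes), capped
  at the recovery time when that is earlier.
* **Recovery time** is the elapsed time from perturbation onset until the
  sway velocity stays below 0.86 deg/s for at least 0.5 s; the reported time
  is the *start* of the quiescence window. Undefined recoveries (criterion
  never met before the trace ends) are reported as missing (`NA`), never as
  a sentinel value.
* Sway velocity is a central finite difference on the timestamp grid.
  Optional zero-phase low-pass smoothing (2nd-order Butterworth, forward and
  backward) can be applied to the angle before differencing; it is off by
  default because differencing a clean 30 Hz stream needs none, and it is
  recommended (≈1.5 Hz cutoff) for noisy angle streams, where differentiation
  amplifies high-frequency noise far above the 0.86 deg/s threshold.
* Velocity is computed per plane on `q_sway` (the threshold is stated in
  deg/s), not on the planar CoM path.

Per-condition summaries are the arithmetic mean and sample standard
deviation (n − 1) over the accepted repetitions — five in a complete
session.

## The synthetic-data generator

No recordings are distributed with the package, so `generate_session()`
fabricates complete sessions with exact ground truth: a 30 Hz force stream
with per-axis bias (removed by the 2000-sample calibration), two IMU
quaternion streams, the garment's four-most-active stream with per-sensor
baselines (thresholded by the 200-sample calibration), and a joint-angle
stream.

The postural response is the impulse response of a linear second-order
system, `q_sway(t) = gain · impulse · h(t)`, critically damped by default
(`response_model(gain = 0.1, omega_n = 4, zeta = 1)`). Rationale:

* It is the minimal model with closed-form peak and decay, so every
  simulated trial carries analytic ground truth for both indicators.
* Critical damping makes the velocity tail monotone, so the 0.86 deg/s
  quiescence criterion has a single well-conditioned crossing. Underdamped
  responses (`zeta < 1`) are supported, but near-tangent velocity peaks can
  alias on a 30 Hz grid and make the recovery time ill-conditioned at
  machine level — a property of the criterion, not of the implementation.
* The defaults give peak sways of roughly 1.5–3° and recovery times of
  1–2 s for pushes of 6–10 % of body weight lasting ≈0.35 s, which is the
  scale reported for healthy perturbed stance.

Joint angles are constructed so that the CoM model reproduces the target
sway *exactly*: AP responses are a pure ankle rotation (a rigid rotation
about the ankle makes the sway angle equal the ankle angle identically), and
ML responses invert the frontal model numerically (monotone
4001-point grid + linear interpolation, error far below the sampling error)
to place the sway at the hip.

Pushes are raised-cosine by default. Because the measured duration is the
supra-threshold time, the generator plans that quantity and widens the pulse
support by the analytic sub-threshold tail fraction. Valid events draw
magnitude within ±1 % of the band centre, supra-threshold duration in
0.30–0.42 s, pitch/yaw within ±10° of the zone's perpendicular; onsets are
6 s apart (the protocol requires ≥ 3 s). Injected invalid events violate
exactly one controlled variable — magnitude 12 % (between the two bands),
duration 0.65 s, yaw ±45° off, or a wrong delivery zone with bleed disabled —
while a wrong-zone push keeps the condition-nominal orientation so only the
location check fails. A condition block always ends with its fifth valid
repetition, because the real protocol moves on the moment it is recorded.

Noise models: additive white Gaussian noise per force axis and per garment
sensor, small random rotations on the quaternions, and white angle noise on
the joint streams. The defaults (0.2 N, 0.1 raw units, 0.2°, 0.02°) reflect
the jitter of the sensor classes involved; the signal-to-noise ratio used in
the verification runs is defined on the RMS power of the sway response over
the analysis window, the standard definition. Stochastic verification
summaries use the median across trials: at 20 dB the noise-induced velocity
fluctuations are of the order of the 0.86 deg/s threshold before smoothing,
so individual trials can legitimately miss the quiescence window by more
than the nominal tolerance while the central tendency is stable.

What the generator does **not** emulate: reflexive multi-joint
coordination, mixed hip-plus-ankle strategies, stepping responses, garment
sensor cross-talk beyond a single-sensor bleed, IMU drift, or asymmetric
left/right kinematics. Passing tests therefore demonstrate that the
processing chain is correct and well-conditioned, not that the simplified
kinematic model captures every real response.

## Verification problem sizes

The test suite and the acceptance script use: 100 random postures against a
10⁴-point-mass discretization oracle per segment (agreement < 10⁻⁶ m); sweep
resolutions of 2.5 ms (duration), 0.1° (pitch), 0.02 % (magnitude) and
bisection to 1 mN / 0.5 mdeg/s for the two thresholds; 50 simulated trials
per noise condition for indicator recovery; and one full 16-condition
session with 10 % injected violations for the end-to-end bookkeeping check.

## Known limitations

* The CoM model is planar; out-of-plane coupling between AP and ML responses
  is ignored, and foot/heel lift is not modelled (trials where the subject
  steps are outside the model's assumptions).
* Recovery time is undefined on traces that never settle; summaries report
  how many repetitions were undefined rather than imputing.
* The duration controlled variable inherits the ±1-sample quantization of
  the 30 Hz logger.
* Garment location uses zone votes of the four-most-active reports;
  simultaneous pushes in two zones (not part of the protocol) would resolve
  to the stronger zone with a deterministic tie-break (protocol order).
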