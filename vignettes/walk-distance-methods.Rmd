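---
title: "Estimating total walk distance from foot-worn IMUs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating total walk distance from foot-worn IMUs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkdist)
```

## The estimation problem

Clinical walking tests report the total distance walked, measured manually
with floor markings and lap counts. A foot-worn inertial sensor records
body-frame acceleration (gravity included) and angular rate; turning those
signals into a distance requires dead reckoning — double integration of
acceleration — which diverges within seconds unless the integration is
anchored. The anchor used here is the structure of gait itself: once per
stride the foot is flat on the ground and its velocity is exactly zero.
These *foot-flat* periods allow zero-velocity updates (ZUPT) that reset the
accumulated velocity error, so the per-stride displacement is estimated
essentially drift-free.

The distance definition is deliberately minimal. With `v(t) = [x, y, z]ᵀ`
the Earth-frame foot position and `t_1 < … < t_N` representative times of
the `N` detected foot-flat periods, each stride contributes the horizontal
chord

$$d_i = \sqrt{(x(t_{i+1}) - x(t_i))^2 + (y(t_{i+1}) - y(t_i))^2},$$

and `d_total = Σ d_i`, turns included. Both feet are processed
independently and the reported distance is the mean of the two totals.
Three properties follow directly and are enforced by tests:

- **Insensitivity to detection errors.** A missed foot-flat merges two
  chords into one chord no longer than their sum; the total can only
  decrease, never jump.
- **Yaw invariance.** Chords are horizontal norms, so the unobservable
  heading (no magnetometer is used) cannot affect the result.
- **Chord ≤ arc.** Integrating the horizontal speed instead (implemented as
  `arc_length_distance()` for comparison) follows the curvature of the
  swing path and always gives a larger number than the chord sum; clinical
  reference distances are straight-line, so the chord definition is the
  right comparator.

## Pipeline stages and their assumptions

**Orientation** (`estimate_orientation()`). A complementary filter
propagates a body-to-Earth quaternion with the midpoint angular rate of
each sampling interval and applies a proportional correction (gain `kp`,
default 2 s⁻¹) that pulls the predicted gravity direction toward the
measured accelerometer direction. The correction is gated: it is applied
only while `|a|` is within 0.9–1.1 g *and* the gyro magnitude is below
0.3 rad/s. The gyro condition matters: during swing the accelerometer
magnitude sweeps through 1 g while measuring mostly kinematic acceleration,
and an ungated filter tilts toward it, leaking gravity into the horizontal
channels. Initial tilt comes from the mean accelerometer over the first
0.25 s (walking tests begin standing still); initial yaw is zero. The gyro
bias is estimated as the mean gyro over all detected stationary samples and
subtracted before propagation. Gravity is fixed at 9.80665 m/s².

The midpoint-rate propagation is not cosmetic: with left-endpoint rates the
attitude lags the true attitude by half a sample, which at 128 Hz produced
a systematic ≈0.3 % underestimation of stride length in noise-free
simulation; with midpoint rates the residual pipeline error drops to
≈0.01 %.

**Foot-flat detection** (`detect_foot_flat()`). A sample is "still" when
the gyro magnitude is below 0.5 rad/s and `||a| − g|` below 0.5 m/s²; a
sample is stationary when every sample in a centred 0.05 s window is still
(an erosion, so isolated noise cannot seed an interval). Runs shorter than
0.05 s are dropped; runs separated by less than 0.05 s are merged. Each
interval's representative time `t_i` is its midpoint — the foot is static
throughout the interval, so any in-interval convention works; the midpoint
is symmetric and stable. The thresholds were chosen on the simulator (no
recorded dataset ships with the package) and are config-exposed
(`zupt_params()`); shrinking them can only shrink or remove intervals.

**Trajectory** (`integrate_trajectory()`). Trapezoidal integration at the
recording rate. Within each stationary interval the velocity is pinned to
exactly zero. Between consecutive intervals the velocity is integrated from
zero and the terminal residual — the accumulated drift of that segment — is
removed by subtracting a linear-in-time ramp, the classic linear
de-drifting scheme; position follows by integrating the corrected velocity.
Samples before the first and after the last stationary interval are
integrated one-sidedly (backward and forward from the nearest anchor), but
chords only ever read positions at foot-flat times, so these unanchored
stretches never enter the distance. With no detected intervals at all the
uncorrected double integral is returned with an explicit warning. Positions
at `t_i` are read from the nearest sample without interpolation: during
stance the position is constant to first order, so sub-sample interpolation
would add machinery without accuracy.

**Bilateral averaging** (`bilateral_total()`). The two feet see the same
walk, so their totals agree closely; if they differ by more than 10 % a
quality warning is attached (the average is still reported — the
single-number contract stands, the warning flags the recording for review).
With only one usable foot the other total is reported with a warning. The
two feet may detect different numbers of foot-flat periods; averaging the
*totals* rather than pairing strides sidesteps any correspondence problem.

## The gait simulator

`simulate_walk()` exists so that every stage has an exact oracle. Foot
motion is composed of phases with closed-form kinematics:

- **stance dwells** — position and attitude constant, velocity exactly zero;
- **swings** — minimum-jerk (quintic) horizontal displacement, `sin³`
  vertical lift (default apex 0.05 m) and a `sin³` sagittal pitch bump
  (default 0.35 rad): position, velocity and acceleration are all
  continuous across phase boundaries;
- **turns** — either a *pivot* (heading rotates ~π during an extended
  stance, adding no chord length) or an *arc* (3–5 short strides along a
  semicircular cap of default radius 0.5 m, whose chords genuinely add
  distance, as they do in real walkway tests).

Body-frame signals follow from the exact inverse sensor equations:
`a_body = R(q)ᵀ (a_earth + g ẑ)` with `R = R_z(yaw) R_y(pitch)`, and the
gyro from the analytic attitude rates. White noise and constant biases are
added per `noise_model()`; a given seed reproduces recordings bitwise.
Defaults (stride 1.3 m, cadence 0.9 strides/s per foot, stance fraction
0.35) are plausible fast-walk values; protocols mirror the two standard
tests: fixed-distance (20 m walkway, 400 m of straight walking = 20
lengths) and fixed-time (6 minutes on a 15 m or 20 m walkway, which lands
in the 300–700 m range typical of fast 6MWT cohorts).

Simplifications worth knowing: the two feet walk parallel tracks offset
±0.06 m from the midline with a half-cycle phase lag, rather than
alternating around a shared line; swing profiles are identical from stride
to stride (no natural variability); noise is white and biases constant (no
random-walk bias instability); and the pivot turn rotates about the sensor
axis, so its stance stays perfectly still. Consequently, passing the
simulator round trips demonstrates correctness of the *method and its
implementation* under its own assumptions — orientation tracking, ZUPT
anchoring, integration, chord summation — not robustness to everything real
feet do (soft-tissue wobble, sensor saturation at hard heel strikes,
shuffling gait). One documented real-world failure mode, foot accelerations
exceeding the sensor bandwidth at very fast barefoot walking, is exactly
the kind of effect the simulator's smooth profiles do not produce.

## Agreement statistics

`fixed_distance_error_pct()` implements the fixed-course metric (mean of
`100·|fixed − d_j|/fixed`, with the signed variant alongside);
`average_absolute_error_rate()` the fixed-time metric
`100·mean|manual − digital| / mean(manual)`, which is scale-invariant.
Bland–Altman differences are **digital − manual**, so a negative bias means
the algorithm underestimates; published reports are not always explicit
about this direction, so the package fixes and documents its own convention
rather than guessing. Limits of agreement are bias ± 1.96 SD with
t-based confidence intervals (`SE(bias) = SD/√n`,
`SE(LOA) = √(3 SD²/n)`); the identity (upper + lower)/2 = bias holds by
construction and is asserted in tests. `icc21()` computes the two-way
random-effects absolute-agreement single-measure ICC from the ANOVA mean
squares, with the exact F-based McGraw–Wong confidence interval; tests
check it against an independent `aov()`-based computation and a frozen
value from an external reference implementation. With a constant ratings
matrix the ICC is undefined (zero between-subject variance) and an error is
raised rather than a number invented.

## Numerical and interface choices

- Canonical units are m/s² and rad/s; CSV readers convert declared `g` and
  `deg/s` on ingest. The interchange format is CSV with `# key: value`
  metadata headers — proprietary vendor formats are out of scope.
- Timestamp jitter above 10 % of the nominal period triggers linear
  resampling to an exact grid before the fixed-step integrators run.
- Quaternions are Hamilton, scalar-first, body→Earth, renormalized every
  step; Earth frame is z-up with arbitrary fixed heading.
- Degenerate inputs fail loudly: fewer than 2 samples, non-monotone time,
  non-finite values, empty foot-flat sequences (warning + uncorrected
  output), fewer than 2 foot-flats (empty chord list), both feet missing
  (error).
- Test problem sizes are chosen to exercise every code path at desk scale:
  10-stride walks for exhaustive properties, a full 400 m protocol across
  20 noisy seeds for the end-to-end accuracy envelope, 256 Hz sampling for
  the quadrature oracle. The independent integration oracle is cumulative
  Simpson (error O(h⁴)), so its own error cannot mask trapezoidal-scale
  defects in the implementation.

## Known limitations

Heading is unobservable, so absolute trajectories are only defined up to
yaw — irrelevant for distance, fatal if you wanted a map. The linear
de-drift assumes the velocity error grows roughly linearly between
stances; very long swing phases or strongly colored accelerometer noise
would violate that. No claim is made of equivalence with any proprietary
implementation of the same idea; the pipeline is validated against its own
simulator and the published summary arithmetic it reproduces.
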