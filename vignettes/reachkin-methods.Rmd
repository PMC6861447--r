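---
title: "Wrist-IMU reach kinematics: models, pipeline and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrist-IMU reach kinematics: models, pipeline and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single low-cost wrist-worn inertial sensor (3-axis accelerometer ±4 g,
3-axis gyroscope ±500 deg/s, 100 Hz) records healthy adults and stroke
survivors performing standardized upper-limb tasks: transferring a block to a
shelf, pantomiming a drink, and pouring water between cups. Three clinical
metrics summarize each trial: **total movement time** (onset to offset, ms),
**peak velocity** (maximum resultant speed, m/s), and **spectral arc length**
(SPARC, a dimensionless smoothness measure; more negative = less smooth).
The package implements the full inertial processing chain, a parallel
optical-marker reference chain (3-D wrist marker at 200 Hz, 1 mm class), the
concurrent-validity statistics that compare the two (Pearson *r*, ICC(2,1)
with F-based CI, Bland-Altman bias/limits of agreement), and a seeded
simulator that generates paired recordings with exact ground truth so every
stage is testable without hardware.

## The inertial chain

1. **Orientation.** A Madgwick gradient-descent attitude filter (IMU variant,
   no magnetometer) integrates the gyroscope quaternion rate and corrects it
   towards the accelerometer's gravity direction at `beta` rad/s. Heading is
   unobservable without a magnetometer, but every metric is computed from the
   resultant (magnitude) velocity, so heading drift is inert. The initial
   orientation comes from the mean accelerometer vector over the first 100
   frames (the protocol guarantees a stationary, pronated start).

   *Why `beta = 0.01` and not Madgwick's generic 0.1:* the gain sets the rate
   at which the filter trusts the accelerometer. During a sustained reach the
   measured specific force is gravity plus up to 0.3 g of movement
   acceleration; at `beta = 0.1` the filter tilts toward that combined vector
   fast enough to leak several percent of gravity into the motion axis, which
   biases peak velocity by up to −10% even on noiseless input. Madgwick's own
   tuning rule, `beta = sqrt(3/4) x mean gyro error`, gives ≈0.008 for the
   0.5 deg/s gyro noise of this sensor class; we round to 0.01. The gain is
   in the configuration for sensors with different gyro quality.

2. **Earth frame and gravity removal.** Accelerometer samples are rotated to
   the earth frame and 1 g is subtracted from the vertical axis. (The
   subtraction is only meaningful after rotation; with the wrist pronated on
   the table the raw z axis reads ≈1 g throughout.)

3. **Trimming.** The record is cut 100 frames before the first sample
   satisfying the movement-start predicate (angular speed > 10 deg/s, or
   |earth z-acceleration| > 0.7 g, or resultant velocity > 0.1 m/s) and 100
   frames after the last sample satisfying the laxer end predicate
   (5 deg/s / 0.7 g / 0.0025 m/s — putting the sensor down vibrates, so the
   tail is harder to keep still). Trimming needs a velocity, and velocity
   needs orientation, so the filter and a provisional (uncorrected) integral
   run over the full record first and trimming is applied to the derived
   series; the z-acceleration criterion is evaluated on the
   gravity-compensated earth value, both choices the configuration exposes.

4. **Stationary detection.** The resultant gravity-removed acceleration is
   passed through a zero-phase 0.001 Hz Butterworth high-pass; the absolute
   value of that output through a zero-phase 2 Hz low-pass. Samples with
   envelope < 0.05 g are stationary. Signals are reflection-padded before
   each filter pass (a plain forward-backward pass leaves large edge
   transients), and the envelope is computed over the full record before
   slicing to the trimmed window, so no filter edge sits next to the data of
   interest. Two detector refinements are config-exposed:

   * **run-length cleanup** (`min_run = 10` frames, both labels): neither
     rest nor movement can last under 100 ms. A minimum-jerk reach passes
     through zero acceleration exactly at peak speed, so the envelope dips
     there; without the cleanup the dead reckoning would pin velocity to zero
     at the fastest point of slow reaches.
   * **gyro veto** (`gyro_veto_dps = 10`): a sample rotating faster than
     10 deg/s is never stationary, whatever the acceleration envelope says.
     Combining accelerometer and gyroscope evidence is standard in
     zero-velocity-update detectors; the veto is what makes slow translating
     segments safe, because a real wrist always rotates while it reaches.

5. **Sectioning.** The center section runs from the first run of ≥10
   consecutive frames with angular speed > 10 deg/s to the last run of ≥20
   such frames; only this section is searched for velocity peaks. The
   asymmetric run lengths make single-frame gyro spikes and end-of-trial
   vibration inert. Because the rule keys on rotation, the center clips the
   low-rotation fringes of the first and last segments by one or two hundred
   ms; every velocity-peak instant remains inside, and movement onset/offset
   are found on the full trimmed profile, so no metric is affected.

6. **ZUPT dead reckoning.** Within each non-stationary interval bounded by
   stationary samples, acceleration is integrated per axis (trapezoidal rule
   on the actual timestamps). The residual velocity at the interval end —
   which should be zero — is removed by subtracting a ramp linear in time
   (the standard ZUPT drift model; a constant accelerometer bias is removed
   *exactly* by this ramp). Correction is per axis before taking the norm:
   correcting the norm instead would bias speed upward because the norm of a
   zero-mean error is positive. Velocity is pinned to exactly zero on
   stationary samples.

## The reference chain

Marker gaps of 1–9 frames are filled per axis by a cubic interpolating
spline; gaps of ≥10 frames (or touching the record boundary) make the trial
unprocessable — the protocol repeats such trials rather than imputing them.
Positions are then smoothed by a **quintic penalized B-spline**
(third-derivative penalty, ~50 knots/s) whose penalty weight is solved so the
residual mean square matches the *predicted MSE* target (default 5 mm²),
reproducing the parameterization of the Woltring smoother used by optical
pipelines. The quintic penalty matters: it is the choice made for data that
will be differentiated — at equal residual, a cubic smoother leaves a
central-difference velocity noise floor of ~10–30 mm/s, above the
2%-of-first-peak onset threshold (the first reach peak is only ~0.4 m/s, so
that threshold is ~8 mm/s).

When the target exceeds the noise variance estimated from second differences
(`mean(diff(x, differences = 2)^2) / 6`), forcing the residual to the target
would absorb signal, not noise — with 0.5 mm markers it distorts movement
time by ~300 ms — so smoothing is capped at the estimate with a warning.
Velocity is the first-order central difference per axis (exact for quadratic
tracks), and the resultant profile is cropped *by time* to the paired IMU
trial's trimmed window (the two systems share a start clock but run at 200 vs
100 Hz).

## Events and metrics

**Peaks.** Starting at 0.1 m/s, the detection threshold is multiplied by
1.05 for up to 60 iterations; at each level peaks are counted with the
classic `peakdet` rule — a local maximum counts only if it exceeds the
threshold *and* is separated from neighboring troughs by at least the
threshold. A bare neighbor-comparison scan would count every sample-scale
ripple of the integrated IMU speed as a peak; the prominence requirement is
what the canonical MATLAB-style peak detector actually implements, and on
clean profiles the two are identical. The first threshold yielding exactly
the task's expected count (block 3, drink 3, pour 4) wins. If no threshold is
exact and both systems' profiles are available, the largest threshold where
the two profiles agree on a count is used; with one profile, the closest
count at the largest threshold is returned with a warning.

**Onset / offset.** Onset is the threshold crossing (2% of the first-peak
velocity for the reference system, 1% for the IMU) nearest the first peak
whose preceding 50 frames average < 0.05 m/s; offset mirrors it after the
last peak (2% for both systems, 75 trailing frames). "Nearest the peak"
implements the search-backward-from-the-peak semantics; taking the earliest
crossing instead latches onto noise-floor excursions a second before the
movement and produces ~1 s errors. The quiet windows are counted in each
system's native frames, so they span 0.5 s at 100 Hz but 0.25 s at 200 Hz —
a documented consequence of specifying them in frames.

**SPARC.** The speed profile between onset and offset is zero-padded to the
next power of two ≥16× its length (the reference implementation's padding
level; at 4× the arc length is not yet grid-converged), the magnitude
spectrum is normalized by its DC value, the band is truncated at the smaller
of 20 Hz and the highest frequency where the normalized magnitude still
reaches 0.05, and the negative arc length of the curve `(f/f_c, V(f))` is
accumulated over the grid. The measure is invariant to amplitude scaling and
time shifts; through the adaptive cutoff it is mildly resolution-dependent,
which is a property of the published definition, not of this implementation.

## Agreement statistics

Per task and metric: Pearson *r*; ICC(2,1) — two-way random effects,
absolute agreement, single measures — from the ANOVA mean squares, with the
95% CI from the F-based (McGraw–Wong) procedure; Bland-Altman bias,
`bias ± 1.96 SD` limits of agreement, and a difference CV% (SD of differences
over the grand mean — the definition is an interpretation, flagged as such).
Differences are IMU − reference, and peak velocity is reported in mm/s
following the clinical convention. The systematic-error check asks whether
zero lies inside the confidence interval of the *mean* difference,
`bias ± t(0.975, n−1) SD/sqrt(n)`; the Student-t multiplier keeps the test at
exactly the 5% level (the normal 1.96 rejects 5.97% of unbiased data at
n = 30). Note that with nine simultaneous task×metric checks, at least one
rejection is expected ~37% of the time even when no bias exists.

## The simulator

Each trial is a sequence of **minimum-jerk segments**
(`x(t) = A(10τ³ − 15τ⁴ + 6τ⁵)`, peak speed `1.875 A/T`) separated by
stationary dwells, with stationary lead-in/out of 1.5 s. Task templates give
block/drink/pour their expected 3/3/4 submovements with bench-plausible
geometry (the block travels to a 37 cm shelf 25 cm away; drink and pour
distances are documented constants, not measurements). Inter-trial
variability emulates a healthy adult repeating the task: segment durations
and trial amplitude scaled by factors with 12% CV, dwells jittered with
0.1 s SD and floored at 0.3 s (sub-0.2 s grasp pauses are not physiological,
and the processing chain presumes resolvable stationary periods between
submovements). A per-trial accelerometer bias (SD 0.005 g per axis) emulates
residual calibration error. Each segment carries one monotone minimum-jerk
wrist rotation of 15°, alternating in sign (reach with slight supination,
return with pronation): angular speed then peaks mid-segment, exactly where
translational acceleration crosses zero, as on a real wrist — without wrist
rotation the angular-speed sectioning rule would never fire for a purely
translational point sensor, which no real trial resembles.

The IMU forward model rotates specific force (linear acceleration + gravity,
plus an optional speed-proportional tremor vibration, default off) into the
sensor frame, adds bias and seeded Gaussian noise (0.02 g accelerometer,
0.5 deg/s gyroscope), and clips to ±4 g / ±500 deg/s. The marker model
samples positions at 200 Hz with 0.5 mm noise and can blank sub-10-frame runs
to exercise gap filling. Both models are pure functions of the specification
and its mandatory seed. Ground truth (movement time = segment span, peak
velocity = closed-form maximum over segments, SPARC of the noiseless speed at
the IMU rate) is written as a JSON sidecar.

**What the simulator does not emulate:** soft-tissue artifact, marker
mis-labeling, corrective submovements and asymmetric velocity profiles of
impaired reaching, temperature-dependent gyro bias drift, transport jitter
and dropped packets. Passing tests therefore demonstrate the correctness and
internal consistency of the processing chains under realistic noise, not
device performance on patients.

## Numerical choices and degenerate inputs

* Timestamps are seconds from trial start; integration steps come from the
  timestamp vector, not the nominal rate.
* Quaternions are re-normalized every step; a numerically zero correction
  gradient skips the step (normalizing rounding noise would take a full-size
  step in an arbitrary direction at the equilibrium).
* The smoothing penalty is solved by root finding on log10(lambda) with the
  penalty matrix scale-normalized; basis and Gram matrices are built once per
  axis, so each lambda probe is a k×k Cholesky solve.
* Peak plateaus take their first sample. All indices are 1-based inclusive.
* Static-only trials, all-zero signals, gyro exceedances shorter than the
  run-length minima, and marker gaps of ≥10 frames raise typed errors
  (`reachkin_no_movement`, `reachkin_gap_error`,
  `reachkin_unbounded_movement`, `reachkin_undefined_metric`) and never
  produce metrics; batch processing logs and skips failed trials.

## Known limitations

* The two chains are different instruments and retain small relative timing
  biases (movement time +7 to +24 ms depending on task, i.e. 0.2–0.8%,
  driven by the asymmetric 1%/2% onset thresholds interacting with the IMU's
  integrated-noise floor; peak velocity within ~3 mm/s; SPARC within ~0.02).
  These are smaller than the between-device biases the underlying validation
  protocol itself reports, but a mean-difference test on hundreds of trials
  will resolve them.
* The default study scale (60 trials per task) and all thresholds live in
  one configuration object that is serialized alongside reports, so a run is
  reproducible from the configuration and seed alone.

## A worked run

```{r example}
library(reachkin)

dir <- tempfile()
for (task in c("block", "drink", "pour"))
  simulate_trials(task, n_trials = 20, seed = 42, out_dir = dir)

metrics <- process_trials(dir, system = "both")
report <- validate_trials(metrics[metrics$system == "imu", ],
                          metrics[metrics$system == "reference", ])
print(report)
write_report(report, file.path(dir, "agreement.csv"))
```
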