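---
title: "Methods: quantifying and modeling gait synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and modeling gait synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsynergy)
```

This vignette is the package's own account of its methods: the models and
procedures, their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic gait generator does and does not
emulate, and the design decisions taken where more than one reasonable choice
existed.

## 1. The synthetic gait generator

The generator exists so that every downstream stage — segmentation, CRP, DI,
determinant regression, synergy modeling — can be exercised and tested
against known ground truth. A `gait_profile` carries the full parameter set;
group defaults reproduce published group means for healthy, stroke and
unilateral transfemoral-amputee gait: walking speed (healthy 0.92 m/s, stroke
0.18 m/s), per-side hip/knee ranges of motion (e.g. healthy RoM_hip 62.33°,
RoM_knee 44.38°; stroke affected side 41.42°/35.92°) and per-side swing
percentage (healthy 0.53; stroke sound side 0.70). Quantities those summaries
do not report were fixed once, at values a gait analyst would call typical,
and are overridable:

* **Stride duration** is back-computed from speed and a group stride length —
  1.1 m (healthy), 0.60 m (stroke, reflecting the short shuffling stride that
  accompanies 0.18 m/s), 1.25 m (amputee). Cadence is not reported for these
  groups, so stride length is the free parameter chosen.
* **Amputee speed** is not reported; 0.80 m/s is used (typical self-selected
  transfemoral speed).
* **Sampling rate** 100 Hz, **measurement noise** Gaussian with sd 0.5° on
  angle channels, 1 °/s-per-degree on the gyroscope and 0.05 m/s²-per-degree
  on the accelerometer.
* **Inter-subject variability**: each profile parameter is multiplied by an
  independent lognormal(0, 0.05) factor under a subject seed.

**Waveforms.** Both joints are exact sums of `harmonic_count` (default 4)
sinusoids at stride-frequency multiples, so the preprocessing module's
harmonic fit can recover them with zero residual and analytic derivatives
exist. The hip (thigh flexion from vertical) is a positive-cosine stack whose
global maximum falls exactly at heel strike — the property the event-free
segmenter exploits. The knee is the harmonic projection of a two-bump
template (small stance-flexion bump, large swing-flexion peak placed
mid-swing, tracking each side's stance/swing boundary); peak-to-peak
amplitudes are rescaled to the profile RoMs (the located extrema are exact to
a 0.02% grid, giving RoM fidelity well under the 0.1° tolerance asserted in
the tests).

**Pauses as time warps.** Patient gait decomposes hip and knee motion; the
generator imposes this with per-(side, joint) pause windows. A window is
realized by *warping cycle time*: the warp speed is zero inside the window
and one outside, with 5-sample cosine tapers just outside the window edges,
and the warp is renormalized separately over stance and swing so event timing
and swing percentage are untouched. A plain zero-order hold was rejected
because it either clips curve extrema (breaking RoM conservation) or, when
blended back smoothly, erodes the below-threshold region by the blend width;
the time warp holds the angle *exactly* constant inside the window while
still visiting every value of the base curve, so RoM is conserved by
construction and an imposed 30%-of-cycle pause is recovered as DI ≈ 0.30 by
the raw-velocity estimator (tested to ±0.02 at zero noise).

Default pause geometries for the patient groups were sized once so the
generated cohorts reproduce the published *orderings* (stroke DI > amputee DI
> healthy DI; affected > sound), not any exact value.

**Thigh inertial channels.** The thigh IMU is emulated from the thigh
segment angle (taken as hip flexion from vertical): gyroscope = its time
derivative; accelerometer = gravity component plus centripetal (r·ω²) and
tangential (r·α) terms at a 0.25 m sensor offset below the hip, in the
sensor frame (axial, anterior, mediolateral ≈ 0). Pelvis translation is
ignored.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: soft-tissue artifact and sensor drift,
stride-to-stride temporal variability (cycles are identical up to noise
within a trial), ankle kinematics, ground-reaction forces, and genuinely
nonstationary pathological patterns (spasticity-triggered events). Results on
synthetic cohorts validate the *computational pipeline*, not clinical effect
sizes.

## 2. Preprocessing

Cycles are heel-strike to heel-strike. With events absent, heel strikes are
detected as hip-angle local maxima — maximum hip flexion closely precedes
heel strike in level walking — separated by at least half the dominant
period, estimated from the first off-origin autocorrelation peak. Each cycle
is linearly resampled onto an inclusive 0–100% grid of **101 points** (the
count keeps both endpoints on-grid) with the stance/swing boundary at
`100·(toe_off − start)/(end − start)`.

Smoothing ("riding-wave" removal) is harmonic regression: ordinary least
squares on {1, sin(2πkt/100), cos(2πkt/100)}, k = 1..K, default **K = 6** —
enough for the two-peak knee waveform, few enough to suppress measurement
noise. Being a linear projection it is idempotent, its residual is
non-increasing in K, and K > 49 is refused (rank deficiency on 101 points).
Harmonic regression at fixed stride-frequency multiples was chosen over
free-frequency nonlinear sinusoid fitting: for periodic gait the two are
equivalent, and the linear version is deterministic and convex. When a trial
contains several cycles, the *representative* cycle is the one with minimal
RMSE to the within-trial mean curve (configurable; the original analyses
picked one cycle per trial without stating a rule).

## 3. Continuous relative phase

The phase of a cycle is computed from the periodic analytic signal: the
cycle is mean-centered, its discrete Hilbert transform taken on the
101-point grid (FFT construction, `H(cos) = sin` sign convention), and
φ = atan2(H, x) in degrees. The four-quadrant arctangent replaces the
two-quadrant arctan(H/x) form, which cannot represent a full phase cycle.
Signals are centered but *not* amplitude-normalized — phase is already
amplitude-invariant, and centering is the minimal requirement for a
meaningful analytic signal. CRP = φ₁ − φ₂ wrapped to (−180°, 180°];
comparisons report RMSE on wrapped (smallest-angle) differences and the
Pearson coefficient, over whole/stance/swing windows.

Conventions where the field's usage varies (all configuration-exposed):

* **Intralimb** pairing is hip–knee within a limb, hip as signal 1.
* **Interlimb** pairing compares corresponding joints across limbs, sound
  (or right) limb as signal 1, with a per-joint breakdown plus their
  pointwise *circular* mean as the summary series. Interlimb CRP is computed
  on a common time base (both limbs normalized over the reference limb's
  cycles) so the nominal half-cycle offset appears as ≈180°; per-limb
  normalization would cancel it by construction.
* **Patient deviation summaries** are RMSEs against the healthy-group mean
  CRP curve for the same pairing and window. Averaging CRP curves uses the
  circular mean, since interlimb curves sit at the ±180° wrap point where an
  arithmetic mean is meaningless.

Edge effects of the discrete transform are confined to a few grid points;
analytic identities (quarter-period lag → 90°) are asserted away from the
endpoints with a 2° tolerance.

## 4. Decomposition index

A joint is paused when |ω| is *strictly below* 5 °/s (the boundary value
counts as moving). A grid point shows decomposition iff *exactly one* joint
of the hip–knee pair is paused (XOR — both-paused is not decomposition,
taken literally from the definition of one joint moving while the other
pauses). DI_whole is the decomposed fraction of the cycle; DI_stance and
DI_swing are normalized by their own phase durations, so each can approach 1
independently — under whole-cycle normalization their published-scale values
could not.

**Velocity estimation** is the one genuinely delicate numerical choice. At
the default noise (0.5° at 100 Hz) a raw central difference has ≈35 °/s of
noise — the 5 °/s threshold drowns; a truncated harmonic fit cannot
represent a hold plateau at all and rings through it (an imposed 30% pause
reads as DI ≈ 0.11). The default estimator is therefore a **local
linear-regression slope** (Savitzky–Golay order-1 derivative) over a 0.2 s
window: a flat-plus-noise plateau keeps a near-zero slope (residual velocity
noise ≈2 °/s), gait-frequency movement passes unattenuated, and the cost is
edge blur of about half a window at pause boundaries. `method = "raw"`
(exact for noiseless data, used by the zero-noise round-trip tests) and
`method = "harmonic"` are retained.

## 5. Determinants

Candidate predictors are DI_sta, DI_sw, swing percentage, RoM_hip, RoM_knee
and speed. VIFs are computed by regressing each candidate on the others;
condition indices come from the singular values of the unit-length-scaled
design (intercept included). Predictors with VIF > 10 are *reported*, not
auto-dropped (no published exclusion rule; auto-drop is available by flag).
Selection is classical bidirectional stepwise on OLS: enter the smallest
partial-F p-value if ≤ α_enter, then remove any retained predictor with
p > α_remove, repeat to a fixed point, ties broken by column order; both α
default to **0.1**, the published significance level. The exact internals of
the original SPSS runs are not restated anywhere, so the classical procedure
is used.

A consequence worth stating: with α = 0.1 and five independent noise
candidates, at least one noise predictor enters with probability
1 − 0.9⁵ ≈ 41% *regardless of signal strength* — exact recovery of a single
true predictor therefore happens in about 59% of replicates, and that rate,
not a higher one, is what the property tests assert. Recovery of the true
predictor itself is essentially certain in the tested construction.

## 6. Synergy models

**Tasks.** Interlimb: estimate one limb's hip (or knee) angle from the
contralateral limb's hip and knee angles and angular velocities (4 input
channels — the published description names "angles and angular velocities of
one side's limb" without enumerating joints; hip+knee is the documented
reading). Intralimb: estimate the knee angle from the ipsilateral thigh IMU
(gyroscope + 3-axis accelerometer, 4 channels). Inputs are z-normalized with
statistics from *training subjects only* (a guard flag prevents double
normalization); targets stay in degrees. Models consume raw time series at
the trial sampling rate (whether the original analyses used cycle-normalized
sequences is unstated; raw series are the default here), and separate
1-output models per target joint (matching the one-neuron output layer).

**PCA-CLME.** Pooled training samples of [inputs; target] are mean-centered
and eigendecomposed; k is the smallest component count reaching
`variance_target` (default **0.95**, exposed) among numerically nonzero
eigenvalues; prediction is `μ_y + U_y · pinv(U_x) · (x − μ_x)`. With
`variance_target = 1` the full numerical rank is retained, which makes the
reconstruction *exact* for a noiseless linear coupling — the configuration
the exact-recovery tests use, since at 0.95 the retained subspace may drop
informative input directions.

**LSTM.** The forget-gate equations with sigmoid gates and tanh candidate
(the candidate input is not defined in the published equation set; the
standard `g(t) = tanh(W1g x + W2g h(t−1) + bg)` is used), hidden size **50**,
one linear output unit, **50** epochs — the published architecture — with
package defaults for what is unspecified: Adam at 1e-3, MSE loss, training
sequences segmented into non-overlapping 200-sample windows for truncated
BPTT, uniform(±1/√hidden) weight initialization with forget-gate biases at 1,
and internal target standardization (training statistics; predictions
returned in degrees — without it, 50 epochs are largely spent learning the
output scale). Forward pass, BPTT and Adam are implemented in
RcppArmadillo; training is single-threaded and bit-reproducible given the
seed. A non-finite loss aborts with guidance to lower the learning rate.

**Evaluation.** Leave-one-subject-out: one session per subject, model fitted
on the rest, metrics (RMSE, MAE, Pearson, R²) on the held-out subject in
degrees, session seeds fanned out deterministically from a master seed.

**Synthetic couplings.** `make_synergy_cohort()` builds cohorts whose
input–target relationship is known: `linear` (exact affine map — any linear
estimator recovers it), `nonlinear` (the corresponding contralateral joint
angle through a tanh saturation with a gait-phase-dependent gain — outside a
static linear model's reach but learnable from temporal context; this is the
desk-scale construction on which the LSTM-beats-PCA ordering is asserted),
and `noise` (independent white noise — nothing to fit, R² ≈ 0).

## 7. Problem sizes and numerical tolerances

Tests and the acceptance script run at desk scale, chosen to exercise every
code path while keeping the default suite fast: cohorts of 8 (healthy) and 6
(patient) subjects, 4–6 cycles per trial at 100 Hz, 10 seeded replicates for
model-ordering properties, 100 replicates for selection/ordering rates.
Analytic identities are asserted at 1e-6 to 1e-12; discrete-Hilbert phase
claims at 2° away from grid endpoints; generator round-trips at ±2 samples
(events), 0.1° (RoM) and ±0.02 (DI). Published group *values* from the
original subject recordings are not reproduction targets — they depend on
unreleased data; the package asserts the qualitative structure (orderings,
exact recoveries, analytic identities) instead.

## 8. Known limitations

* The generator's cycles are identical within a trial up to noise; metrics
  of stride-to-stride variability would be degenerate on it.
* Event-free segmentation assumes the hip-flexion-maximum heel-strike proxy;
  gait with flat hip profiles (fast running, crouch gait) would need an
  external event source.
* The DI slope estimator blurs pause edges by about half its window; very
  short pauses (< 0.2 s) are attenuated.
* PCA-CLME is strictly affine; its role here is the comparison baseline.
* The LSTM is deliberately compact and CPU-bound; it is not a
  general-purpose deep-learning facility.
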