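---
title: "Methods: inferring whale biology from thermal flukeprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring whale biology from thermal flukeprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flukeprint)
```

## The measurement problem

A dual-sensor drone hovering at nadir over a swimming humpback whale
records two synchronized views of the same events: an RGB stream in which
the body is visible while the whale is near the surface, and a
thermal-infrared (TIR) stream in which each tailbeat's flukeprint remains
visible for some time after the whale has passed. The analysis question is
how much biology the prints alone carry: can print width stand in for body
size, print spacing for swimming speed, and print axis for heading, when
each is validated against the RGB reference?

`flukeprint` operates on *annotation tables* — landmark clicks exported
from measurement software, one row per landmark per frame — not on raw
video. This keeps the package's scope at the statistical procedure and
makes every stage drivable by the built-in simulator.

## Photogrammetric scaling

For a nadir view the ground scale is uniform: one pixel covers
`altitude / focal_length` metres (the ground sample distance, GSD). All
length measurements are Euclidean pixel distances between undistorted
landmarks, multiplied by the GSD. Two choices matter:

- **Undistortion** applies the Brown–Conrady radial polynomial at the
  observed pixel's radius from the principal point,
  `corrected = c + (p − c)(1 + k1 r² + k2 r⁴ + k3 r⁶)`. For the small
  distortions of gimbal-stabilised survey cameras the difference from an
  iterative inversion is far below annotation noise, and the direct form
  is exactly checkable per pixel. Intrinsics are accepted as configuration
  inputs; calibration itself (checkerboard bundle adjustment) belongs to
  external tooling.
- **Oblique frames are rejected**, not corrected. Off-nadir geometry makes
  the ground scale position-dependent; measurement is only defined for
  `nadir = TRUE` flight contexts.

Altitude comes per-record from the annotation table when present (the
`altitude_m` column, mirroring barometric telemetry), falling back to the
flight-level constant.

## The synthetic survey generator

The generator is the package's ground truth. Its defaults describe one
fixed set of study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_adults`, `n_calves` | 80, 12 | class sizes of a season's survey |
| adult body length | N(12, 1) m | adult humpback scale |
| calf length fraction | U(0.30, 0.50) | calves at most half an adult's length |
| fluke span | 0.30 × body length | allometric constant |
| print width | 0.9 × span + class noise | adult SD 0.15 m, calf SD 0.35 m |
| speed | U(0.8, 1.6) m/s | breeding-ground swimming speeds |
| tailbeat frequency | U(0.20, 0.33) Hz | print every 3–5 s |
| sampling | 30 Hz, 90 m ± 0.5 m | dual-sensor survey altitude |
| pixel noise | 1 px | annotation jitter |
| heading noise | 6° TIR, 1° RGB | print-axis reading is the noisier channel |
| `beta0, beta1, sigma_u, sigma_e` | −0.39, 0.33, 0.09, 0.18 | generative spacing→speed model (natural logs) |

The larger calf width noise encodes the biological expectation that
compliant juvenile flukes couple morphology to wake width more loosely
than stiff adult flukes; with these defaults the class width clusters are
disjoint, which is what makes perfect threshold classification the
expected outcome rather than an accident. The generative mixed-model
parameters were chosen once so that, with event spacings drawn log-normal
(sdlog 0.5), the fixed effects explain roughly 40% of log-speed variance
and fixed plus random effects roughly 50% — the regime the method is
meant for, where residual variance dominates the whale intercepts.

Tracks are linear at constant per-event speed (the analysis explicitly
conditions on continuous, linear swimming); prints are deposited every
tailbeat period, so successive centroids are exactly `speed × period`
apart before noise. Noise enters in pixel space: world coordinates are
projected through the per-frame jittered GSD, pixel jitter is added, and
the emitted world coordinates are back-projected from the noisy pixels,
so the two coordinate systems never disagree and the zero-noise limit is
exact to machine precision.

What the simulator does **not** emulate — and therefore what passing
tests do not demonstrate about field data: print growth and deformation
over time (the `emergence_offset_s` quality window is sampled, but width
does not actually degrade with it), overlapping prints from interacting
whales, curved or accelerating tracks, wake hydrodynamics, and
environmental drivers of print persistence. Print-intensity decay in
`render_thermal_frame()` is a visual demonstration with free parameters,
not a physical model.

One visible consequence of the noise model: frame-to-frame RGB speeds are
computed from displacements of ~4 cm at 30 Hz, so 1 px (~1.5 cm) of
annotation jitter inflates the mean RGB speed by roughly 0.2 m/s in the
default simulation. This is a real property of frame-to-frame
differencing under annotation noise; the `stride` argument of
`rgb_track_speed()` (recorded in output, default 1) lengthens the
baseline and shrinks that inflation without changing the default
behaviour.

## Morphometrics and the age classifier

Widths enter per-whale means only when measured within 5 s of fluke
emergence and not flagged degraded; degraded prints remain available to
the kinematics stage. Scaling models are ordinary least squares; the
interaction scope fits `response ~ width * class` and reports the
interaction F test. Cross-validation uses simple random (unstratified)
folds under a caller-supplied seed, and the held-out R² is defined as
`1 − SSE/SST` pooled across folds — a definition that is stable under
re-seeding, unlike per-fold averages on small folds. When a scope has
fewer observations than folds, k silently cannot be honoured and is
reduced to n with a warning.

The classifier is a logistic regression of class on mean width, but its
operating point comes from a direct threshold scan: because the single
predictor is monotone in the fitted probability, scanning width
thresholds is equivalent to scanning probability thresholds and is exact.
Sensitivity and specificity are computed at midpoints between adjacent
observed widths; Youden's J picks the optimum, ties resolved toward the
smallest threshold; the reported threshold is the gap midpoint, a
reproducible convention when a gap (complete separation) makes the
optimum an interval. Complete separation is detected by near-zero
residual deviance and *flagged*, never treated as an error — with
disjoint clusters it is the expected outcome. AUC from the scan equals
the Mann–Whitney statistic (property-tested, and cross-checked against an
independent ROC implementation).

## Speed agreement

Differences are oriented RGB − TIR throughout, the RGB channel being the
visual reference. Limits of agreement use 1.96 × SD of the paired
differences; nRMSE scales by the mean RGB speed; MAPE excludes (with a
warning) pairs whose RGB speed is exactly zero. ICC(A,1) is the
McGraw–Wong two-way random-effects absolute-agreement single-measure
form, computed from explicit sums of squares with k = 2 sensors, with the
F-based 95% interval. Spacing increments are formed only between
consecutive `print_id`s; a gap (a missed print) breaks the chain rather
than silently spanning it.

Deming regression uses the closed-form errors-in-variables slope with
λ = 1: both channels are image-derived speeds with comparable noise, and
no better estimate of the variance ratio is available. Standard errors
are leave-one-out jackknife; calibration is tested as slope = 1 and
intercept = 0 Wald tests. The paired t statistic is undefined for
exactly constant differences (zero variance) and is reported as `NA` in
that degenerate case.

## The spacing-to-speed mixed model

`fit_loglog_lmm()` fits
`log(speed) = beta0 + beta1 log(spacing) + u_i + e_ij` by REML (ML is
available, and is what should be used when comparing fixed-effect
structures such as the optional body-length term, which is off by
default). Natural logarithms are used throughout so the log-normal mean
correction is the familiar `exp(sigma²/2)`. R² follows
Nakagawa–Schielzeth with the fixed-effect variance taken as the variance
of the fixed-effect linear predictor over the data. The random-intercept
variance may legitimately sit at the zero boundary, in which case the
fixed effects coincide with OLS; this is reported, not warned away. With
a single whale the model is unidentifiable and the function falls back to
OLS with an explicit warning.

Still-image prediction propagates three variance sources for a *new*
whale: fixed-effect uncertainty `x'Vx`, the random-intercept variance,
and residual variance. The 95% interval uses the normal 1.96 quantile
without a degrees-of-freedom correction. The bias-corrected mean uses
`exp(eta + (sigma_u² + sigma_e²)/2)` — both variance components, because
the prediction targets an unknown whale; a within-known-whale prediction
would use `sigma_e²/2` alone, a convention documented here because either
reading is defensible.

Leave-one-whale-out CV withholds *all* events of a whale, refits, and
predicts at population level (u = 0): the held-out whale's intercept is
unknown by construction. Calibration of the model's predictions is
well-behaved by design in the simulator, and the package's validation
checks that the empirical 95% interval coverage on a well-specified
simulation of 50 whales × 4 events lands in [92, 97]%, and that over 100
replicates of 36 whales × 2 events the slope estimate falls within 2
reported SEs of the generative 0.33 at least 90 times. Those problem
sizes keep the full validation run to a few minutes on one core while
leaving the Monte-Carlo bands meaningful.

## Orientation

Bearings are geographic compass angles, `atan2(Δeast, Δnorth)` mapped to
[0, 360), computed from world coordinates assumed to be in a local
east-north frame. When only pixel coordinates exist, converting a pixel
vector to a compass bearing requires the frame's north alignment (drone
yaw); the annotation schema carries a `yaw_deg` column to make that
dependency explicit rather than assuming image-up is north.

Wrapped differences live in (−180, 180] with −180 mapped to +180.
Circular SD is `sqrt(−2 ln Rbar)` (reported in both radians and degrees,
since the two are easy to mislabel in small-dispersion data). The
Rayleigh p-value uses Zar's refinement
`exp(sqrt(1 + 4n + 4(n² − Rv²)) − (1 + 2n))`, accurate at small n, with
the asymptotic `exp(−Z)` also reported. The Fisher–Lee correlation uses
the standard asymptotic normal test. Agreement categories use inclusive
upper bounds (≤5°, ≤15°, ≤20°), Discrepant strictly above 20°, and
per-whale summaries accompany the pooled report. Degenerate inputs —
zero resultant length, zero circular variance in a correlation — are
flagged (`NA` plus warning), not errors, because a uniform or constant
heading sample is a legitimate observation.

## Pipeline and reproducibility

`run_pipeline()` chains simulation, morphometrics, speed and orientation,
and writes a JSON report (floats at 6 significant digits) plus CSV tables.
Every random step derives from the seed recorded in the report, and a
repeated run with the same configuration is byte-identical — tested as
such. The package's interface is its functions plus `run_pipeline()`; the
stage names (`simulate`, `morphometrics`, `speed`, `orientation`) are the
pipeline's subcommand vocabulary for callers that want one stage at a
time.

## Known limitations

- The simulator's realism limits transfer: agreement magnitudes obtained
  on synthetic data characterise the *procedure*, not any field system.
- Print width does not deform with print age in the simulator, so the
  5 s quality window is exercised as a filter, not as a bias correction.
- The RGB frame-to-frame speed estimator inherits a positive noise bias
  at high frame rates (see above); stride or smoothing is advisable for
  noisy annotations.
- Orientation from pixel-only annotations requires yaw; without it,
  bearings are image-relative.
- No behavioural segmentation: callers must supply linear-swimming
  segments, as the estimators assume them.
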