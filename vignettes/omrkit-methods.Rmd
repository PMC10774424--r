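---
title: "Models and methods behind omrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind omrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omrkit)
```

omrkit quantifies two linked phenomena in larval zebrafish: the optomotor
response (OMR) — reflexive turning toward whole-field visual motion — and the
trial-structured responses of small neuronal units imaged with a slow calcium
indicator across anesthesia and washout. Because raw tracking and imaging data
of this kind are rarely redistributable, the package pairs every analysis
stage with a synthetic generator whose ground truth is known, so the entire
pipeline can be exercised, calibrated, and regression-tested without any
download. This vignette documents the generative models, the analysis
conventions, the numerical choices, and what passing tests do and do not
establish about real data.

## The behavioral model

A virtual fish swims in discrete bouts. Bout onsets follow a renewal process:
exponential inter-bout intervals plus a 200 ms refractory period, the simplest
generative choice that reproduces order-of-magnitude bout statistics. The
post-refractory hazard is `r/(1 - 0.2 r)` so that the *realized* bout rate
equals the nominal rate `r` despite the dead time. Rates default to 0.5 Hz
without grating motion and 1 Hz during motion, and are multiplied by an
anesthesia gain: 1 for untreated fish, `1 - exp(-t / tau_rec_min)` (default
time constant 25 min) within-session after acute anesthesia, and a hard cap at
50% of control for fish reared under anesthesia.

Each bout draws a signed turn angle (positive = leftward/counter-clockwise,
stated once here and used everywhere) from a mixture of a forward component,
`N(0, 3.5°)`, and a turn component, `±|N(30°, 10°)|`. Under leftward or
rightward motion the turn direction matches the stimulus with probability

```
p_eff(t) = 0.5 + (p_correct - 0.5) * E(t),   dE/dt = (s(t) - E) / tau_int
```

where `s(t)` is 1 during lateral motion and 0 otherwise. The turn-mixture
weight itself scales with `E(t)` from its resting value (0.3) toward its
driven value (0.8): the fish swims mostly forward until evidence for the
motion direction has accumulated.

**Choice of `tau_int`.** The accumulator serves two roles that pull in
opposite directions over a 10-s motion phase. Session-level turn accuracy is
defined over *all* motion-phase turn bouts, so any accumulation transient
depresses the measured accuracy below the asymptote `p_correct`; at the same
time, within-stimulus improvement over the first seconds is a real phenomenon
worth generating. We resolve this by making the *default* integration constant
fast (`tau_int_s = 0.25`): the closed-form integrals of `E(t)` then put the
session-median accuracy within about one percentage point of `p_correct`, so
the printed accuracy targets (96.7% control, 94.9% dark-reared, 55/75/89/93%
by washout duration) can be used directly as generator asymptotes. Analyses of
within-stimulus integration use a slower constant explicitly (the tests use
`tau_int_s = 2`), which produces the characteristic rising accuracy-vs-time
curve. Both regimes use the same equation; only the constant differs.

Other behavioral choices, fixed once:

* **Closed loop is emulated, not rendered.** The experimental rig locks the
  stimulus to the fish's body axis, so stimulus direction is defined in the
  fish frame and heading changes cannot alter it; no visual scene is needed.
* **Bout waveform.** Each bout deposits its heading change and a 0.2 cm
  forward displacement over a 150 ms smoothstep ramp in the 100 Hz tracks,
  giving detection realistic structure without a hydrodynamic model.
* **Forward and backward gratings** drive the motion-period bout rate but
  carry zero turn bias. For backward motion this is an explicit guess — no
  turn statistics are reported for that direction.
* **Dark and strobe rearing** are implemented purely as accuracy defaults:
  dark = 0.949 with a ~3-trial transient starting at 0.94 on the first set,
  strobe = 0.95. The transient relaxes exponentially over sets
  (`trial_transient_tau = 1.5` sets).
* **Washout accuracy** for anesthesia-reared fish interpolates linearly
  between anchors (0–1 h: 0.55, 2 h: 0.75, 6 h: 0.89, 24 h: 0.93) and is
  clamped beyond the last anchor.
* **Tracking noise** defaults to 0.05° heading jitter and 0.002 cm position
  jitter per 100 Hz sample — "default SNR" in the tests. The arena is
  unbounded; wall interactions are out of scope.

## Bout detection and behavioral statistics

`detect_bouts()` thresholds boxcar-smoothed (3-sample) angular speed
(30 deg/s) and translational speed (1 cm/s), merges epochs closer than 20 ms,
discards epochs shorter than 30 ms, and measures each bout's turn angle as the
heading change across the epoch padded by 30 ms. At default SNR this recovers
the generator's ground truth with recall and precision ≥ 0.99 and sub-degree
angle error; thresholds were chosen from the waveform and noise scales, not
fitted.

Turn statistics follow fixed conventions: turn histograms use 5° left-closed
right-open bins over [−180°, 180°); bouts with |angle| ≤ 10° count as forward
swims and are excluded from the correctness denominator (the turn distribution
has a dominant forward mode at 0°, and counting forward swims as incorrect
would bound accuracy far below the observed values); exact-zero angles are
excluded as measure-zero ties. Performance-versus-time curves bin bouts by
time since motion onset into half-open 1-s bins with clock zero at motion
onset; empty bins propagate `NA` rather than being interpolated. All group
summaries are median plus interquartile range, with quartiles computed by
linear interpolation between order statistics (`quantile` type 7).

## The imaging model

Each imaging trial lasts 60 s at 1 Hz: 10 s static grating, 30 s leftward or
rightward motion (randomized, with at least one adjacent left-then-right pair
guaranteed per block), 20 s static. Frame `k` covers time `[k, k+1)` s
(0-based), so motion starts at trial frame 10. Recording blocks are one hour
(60 trials); the acute experiment runs baseline → tricaine → washout blocks,
the lifetime (anesthesia-reared) experiment starts directly in tricaine.

A unit (a cluster of 1–5 similarly tuned neurons) has a stimulus drive that
relaxes toward its amplitude with time constant `tau_on_s` while motion in its
preferred direction(s) is on, and back toward zero with `tau_off_s` otherwise.
Suppressed units receive negative drive; motion-selective units respond to
both directions. The drive is filtered by the calcium-indicator impulse
response, a single-exponential decay with a 1.8 s constant (GCaMP6s-like,
configurable); at 1 Hz sampling a more detailed rise model is unidentifiable.
Fluorescence is

```
f(k) = baseline_f + gain(t) * (kernel ⊛ drive)(k) + noise
```

with `gain` exactly 0 in tricaine blocks, 1 in baseline blocks, and a logistic
`1/(1 + exp(-(t - x0)/k))` in washout time — deliberately the same form the
analysis fits, making recovery-parameter estimation well-posed (robustness to
a non-logistic gain can be probed through the `gain_fun` override). An
optional multiplicative background flicker can be added during tricaine blocks
to emulate stimulus-uncorrelated residual signal. Drive and filter states are
propagated *exactly*: both are linear first-order systems with
piecewise-constant input, so each frame applies a closed-form affine update
and reports the within-frame time average, vectorized across the population.
A test checks this propagator against an independent ODE solver. Drive and
indicator state carry over between trials, as they do with slow indicators;
onset constants below the frame interval are allowed but flagged sub-frame.

Amplitudes in sampled populations are log-normal around 300 fluorescence
units, with a configurable fraction of weak units below the fittable
threshold; washout midpoints are normal around 45 min (acute) or 90 min
(lifetime cohorts), reflecting the slower clearance after prolonged
anesthesia.

## Trial responses and indices

The response metric is `C − C0`: the per-trial baseline `C0` is the mean of
the 10 pre-motion frames and is *subtracted*, never divided by, because a
baseline of zero is common in silenced recordings and must remain valid input.
The baseline-window mean of every `C − C0` array is exactly zero by
construction. The scalar trial response averages `C − C0` over the entire
trial by default; a motion-window variant is available because trial-average
figures are usually motion-locked.

The responsiveness index divides each trial's scalar response by the unit's
own maximum absolute trial response across *all* trials of the multi-hour
experiment (not per block), preserving sign: net-increasing units peak at
exactly +1, net-decreasing units at exactly −1, and the per-unit
normalization is what makes silenced-block values look noisy — low activity
becomes indistinguishable from no tuning. Whether the increase and decrease
branches should be rescaled separately is not determinable from the published
description; max-absolute with sign preservation is adopted and isolated in
one function. A unit's class is reported as the sign of its summed trial
responses.

The direction-selectivity index (DSI) matches adjacent left-then-right trial
pairs in schedule order (literally "first leftwards, followed by rightwards";
non-conforming adjacencies are skipped and pairs never overlap), takes the
difference of the two scalar responses, and normalizes by the unit's maximum
absolute pair difference: +1 is leftward-selective, −1 rightward-selective.
Units whose maximum per-frame `C − C0` never exceeds 100 fluorescence units
(strict inequality) are excluded from kinetics fitting.

## Curve fitting

All fitters share deterministic machinery: 8 initial guesses derived from data
quantiles, Levenberg–Marquardt least squares, best residual sum of squares
wins, ties broken by the smallest time constant. Identical inputs always give
identical fits. Degenerate inputs (flat, all-zero) return `converged = FALSE`
rather than parameters.

* **Bout-rate recovery**: `r_inf (1 - exp(-(t - t0)/tau))`, zero before `t0`;
  the delay `t0` is free by default and can be fixed to 0.
* **Logistic recovery**: `A / (1 + exp(-(t - x0)/k))` with `k` parameterized
  as a time constant (a denominator scale, not a slope). Decreasing series
  are fitted in mirrored orientation and flagged `negative_slope`.
* **Onset/offset kinetics** are fitted on trial-averaged responses (single
  trials at 1 Hz are too noisy): the onset rise `c_max (1 - exp(-t/tau_on))`
  on motion frames and an exponential decay on post-motion frames with
  `c_max` re-estimated. The forward model includes the indicator kernel and
  per-frame averaging by default, so the constants refer to the underlying
  drive. `audit_kernel_bias()` measures recovery error across a grid of
  constants for both the kernel-aware and the plain fit: the plain fit
  inherits a bias on the order of the kernel constant (tens of percent),
  while the kernel-aware fit stays within 5% everywhere on the audited grid —
  that audited 5% is the package's documented kinetics tolerance. Bounds are
  `tau_on ∈ [0.05, 30]` s and `tau_off ∈ [0.1, 60]` s; estimates at a bound
  are flagged `unresolved`, and onset estimates below the frame interval
  `sub_frame`.

## Statistics

Group comparisons use the two-sided two-sample Kolmogorov–Smirnov test, the
Wilcoxon–Mann–Whitney rank-sum test, or the Kruskal–Wallis omnibus test, as
appropriate. Effect sizes are always absolute differences of medians in the
metric's native units, never test statistics. No multiple-testing correction
is applied by default, matching the reporting style the package mirrors;
users who want one can adjust the returned p-values with `p.adjust`.

## Verification strategy and problem sizes

The test suite checks each stage against an independent oracle: binomial and
Poisson interval checks on generator counts, closed-form and ODE-solver
checks on the accumulator and the imaging propagator, hand-constructed
tracking for bout detection, counting oracles for histograms and proportions,
and self-consistency at 1e-6 relative error for every fitter on noiseless
model data. End-to-end checks run at the sizes the package treats as its
standard experiment: 30 fish × 30 sets per rearing condition for accuracy
recovery (±2 percentage points), 50 replicate acute sessions for the 25-min
rate-recovery constant (±10%), populations of 147 (acute) and 134 (lifetime)
units for tuning recovery, 100 replicate cohort pairs for the 45-vs-90-min
onset ordering, and 2000 replicates for type-I-error calibration of the three
tests within [0.03, 0.07] at α = 0.05.

## What the synthetic data do and do not show

The generators emulate bout-structured swimming with stimulus-conditioned
turn bias, anesthesia-dependent rates, and trial-structured calcium responses
with known tuning, kinetics, and recovery — the features the analyses
measure. They deliberately omit biomechanics, visual rendering, wall
interactions, kinematic bout types, motion artifacts, z-drift,
photobleaching, spiking biophysics, and source-extraction problems
(segmentation is replaced by known ROI boxes). Passing tests therefore
demonstrate that the *analysis pipeline* is correct and well-calibrated under
the stated noise models; they do not validate preprocessing steps (motion
correction, segmentation) that real recordings require upstream, and
real-data effect sizes need not match the generator defaults.
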