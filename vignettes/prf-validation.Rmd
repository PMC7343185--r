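---
title: "Validating pRF estimators by parameter recovery"
author: "prfval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating pRF estimators by parameter recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfval)
```

## The model and its assumptions

A voxel's population receptive field (pRF) is modeled as a 2-D Gaussian
over the visual field. The forward model is linear: the binary stimulus
aperture is projected through the receptive field frame by frame, the
resulting neural response is convolved with a hemodynamic response function
(HRF), scaled to percent signal change (PSC), and additive noise is
superimposed. The reference estimator inverts exactly this model for the
circular Gaussian — the base case every published pRF tool can fit — with
the amplitude (gain) and baseline handled as free linear parameters.

Three assumptions matter for interpreting everything below. First,
linearity: no compressive spatial summation, so doubling the field's gain
doubles the noise-free modulation exactly. Second, the Gaussian is
unnormalized (its peak equals the gain); the fitted gain absorbs overall
scale, so position and size recovery are unaffected by this convention.
Third, the synthesizer and fitter deliberately share one forward-model
implementation. That makes noise-free matched-HRF recovery a *calibration*
of the loop (it must be exact to optimizer tolerance), while the
interesting results are what happens when the synthesis assumptions and the
analysis assumptions differ.

## Geometry and stimulus

The default visual-field grid spans 20 degrees with 101 samples per axis
(0.2 deg/sample); odd sample counts put the central sample exactly at
fixation. The default stimulus is a 2-deg-wide bar sweeping along four
motion axes in both directions (8 sweeps) at 18 s per sweep with 1 s
frames, with 14 s blanks after every second sweep: 8·18 + 4·14 = 200
frames. The bar-width and schedule defaults are configurable; the schedule
is an explicit design choice of this package, not a claim of
bit-compatibility with any published generator. Slower protocols (28, 38 s
per sweep) keep the frame rate and lengthen the movie, scaling blank
length with sweep duration so the structure is preserved. Randomized
designs permute the frame order of the sweep movie (blanks included) under
a seed: sweep and randomized stimuli therefore contain identical frame
multisets and are signal-matched except for temporal order, which is what
makes their comparison clean.

## HRF families

Two kernel families are provided. The canonical two-Gamma form is the peak
Gamma density minus a scaled undershoot (`a1 = 6, b1 = 1, a2 = 16, b2 = 1,
c = 1/6` by default); the Boynton form is a delayed single Gamma with no
undershoot (`n = 3, tau = 1.5 s, delay = 2.25 s`), which makes
width-mismatch effects easy to see. Kernels are sampled at the stimulus
frame rate over 40 s and normalized to unit sum, so convolution preserves
the series mean and HRF mismatch perturbs response *shape* only — gain is
a free fit parameter regardless. `hrf_scale_width()` dilates a kernel in
time, scaling full width at half maximum (FWHM) and peak time together.

The four-member family used for mismatch matrices (`default_hrf_set()`)
deserves its own paragraph, because the obvious construction is wrong.
Pure time dilation scales FWHM, but it scales onset and peak latency by
the same factor; with a 3–4× width range the *latency* mismatch between
synthesis and analysis kernels dominates the fit. A temporal misalignment
cannot be absorbed by shifting the center (bidirectional sweeps make the
implied shifts cancel), so the optimizer absorbs it by inflating sigma in
*both* mismatch directions — destroying the monotone width–bias
relationship and dragging centers outward. We therefore build the family
by scaling the Boynton time constant (`tau = 1.5·w`, `w ∈ {0.75, 1, 1.25,
1.55}`, FWHM ≈ 3.8/5.1/6.4/7.9 s — a realistic range for published tool
defaults) while adjusting the onset delay so every member has the same
mean response latency (first temporal moment, 7.5 s). Center estimates
couple to the kernel's mean latency, so the aligned family isolates the
width effect on size from latency effects on position. With it, the
classic result appears cleanly: synthesizing with a narrower HRF than the
analysis assumes shrinks the estimated radius, a wider one inflates it,
and only the matched condition is unbiased.

## Noise model and presets

Noise is additive in PSC units: Gaussian white noise plus three
quasi-periodic components — cardiac (1.2 Hz), respiratory (0.3 Hz) and
low-frequency drift (0.01 Hz) — each a sinusoid whose frequency and
amplitude are jittered per realization (uniform ±5% frequency, ±10%
amplitude by default; ±30% frequency for drift) with a random phase. At a
1 s frame interval the cardiac component aliases, as it does in real
acquisitions. Realizations are pure functions of (spec, length, dt, seed).

The low/mid/high presets were calibrated once, in-package, so that their
realized SNR against the default noise-free reference signal (circular pRF
at (3, 3) deg, sigma 2 deg, 10% peak modulation) sits near the values
observed for single-acquisition visual-cortex data: about +5.3, −0.5 and
−4.3 dB (200-seed medians: 5.28, −0.50, −4.29 dB). SNR is defined as
`20·log10(rms(signal)/rms(noise))`. The preset parameter values themselves
(white sd and component amplitudes, roughly 2:1:1:2.3 white:cardiac:
respiratory:drift in amplitude) are original to this package; only the
resulting SNR levels are anchored externally. Tests assert the strict
low > mid > high ordering rather than exact dB values.

The calibration module implements the block-design procedure such presets
are derived from on real data: select voxels whose mean signal exceeds 75%
of the grand mean, keep those within 80% of the maximum spectral coherence
at the stimulus frequency (amplitude at the stimulus bin over the mean
amplitude in a ±10-bin window), convert to PSC and keep modulations of
8–12%; then fit the whole-run sinusoid and take the residual as the noise
estimate. Two readings in that procedure were genuinely open and are fixed
here by explicit choices: "modulation" is peak-to-peak/2 of the PSC series
(the literal mean of max and min is ≈0 for a zero-mean series and is
rejected), and reference voxels are picked at configurable quantiles of
the survivor noise distribution (default 95/45/10%).

## The estimator and its numerics

`prf_fit()` runs a coarse grid search — centers on a 1-deg lattice over
±10 deg, sigma in {0.5, 1, 2, 4, 8} deg, gain and baseline solved in
closed form at every node — followed by bounded L-BFGS-B refinement of
(x0, y0, sigma) within x, y ∈ [−20, 20] and sigma ∈ [0.1, 10], from the
best node and two seeded perturbations of it (three starts). Grid-search
ties (objectives within 1e−12) break toward smaller sigma, then smaller
eccentricity, then x/y order, making degenerate geometries deterministic.
An all-constant series short-circuits to a flagged zero-gain result;
negative-gain winners are flagged as degenerate fits. The refinement
objective tolerance is 1e−6 on the RMSE; the refined solution is never
accepted if worse than its initialization. For noisy data,
`aggregate_median()` repeats the fit with different start seeds and takes
component-wise medians — a practical outlier suppressor given that
nonlinear pRF searches occasionally return local minima.

Convolution is causal direct summation with zero stimulus history before
the first frame, truncated to the stimulus length; the same routine serves
synthesis and fitting, so the two sides agree to machine precision rather
than "approximately".

## What the synthetic data does and does not emulate

The generator reproduces the statistical structure that matters for
validating pRF estimators: known receptive-field parameters, realistic
temporal SNR, HRF variation, and stimulus-design effects. It does not
emulate spatial structure — voxels are an indexed list (one-dimensional
NIfTI convention), with no anatomical geometry, no spatially correlated
noise, no motion, and no multiplicative or input-referred (eye-movement)
noise. Passing tests therefore demonstrate estimator correctness and
sensitivity to the modeled factors; they do not certify performance under
artifacts the generator omits. DoG receptive fields are synthesized but
only the circular Gaussian is fitted, matching the validation scope.

## Study conditions and problem sizes

The validation experiments run at the reference conditions: ground truth
(3, 3) deg, sigma 2 deg, 10% peak modulation, default stimulus. The noise
study uses 25 repetitions per noise level with a fixed master seed and
per-voxel seeds derived by a counter (`masterSeed + voxelIndex`), so any
voxel is reproducible in isolation; the mismatch experiments are
noise-free and need one voxel per condition. These sizes give stable
medians and quantile widths for the properties asserted (center accuracy,
ordered spread, monotone bias) while keeping a full run in minutes on one
core. The 90% coverage ellipse is the sample-covariance ellipse scaled by
the chi-square(2) quantile; its nominal mass is verified empirically on
10^4 seeded bivariate normal draws. Report trimming is rank-based (the
central `ceil(0.9·n)` order statistics of the sigma estimates), so a
degenerate distribution still yields the documented trimmed-set size.

## Known limitations

Elliptical and DoG *fitting*, compressive summation and HRF-parameter
estimation are out of scope (synthesis supports the first two). The noise
presets are calibrated stand-ins anchored to published SNR levels, not to
any specific scanner. The bar-sweep schedule is a documented default, not
a reproduction of any particular lab's protocol; conclusions about
mitigation (slower sweeps, randomization) are about these protocol
families, not exact published stimuli.
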