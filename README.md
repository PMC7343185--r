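# prfval

Parameter-recovery validation for population receptive field (pRF) mapping
with fMRI.

In pRF mapping, a voxel's aggregate receptive field is modeled as a 2-D
Gaussian `G(x0, y0, sigma)` over the visual field. The measured BOLD series
is predicted by a linear forward model: the binary stimulus aperture movie
`S(x, y, t)` is projected through the receptive field,

    r(t) = sum_xy S(x, y, t) * G(x, y),

convolved with a hemodynamic response function (HRF) `h`, scaled to percent
signal change, and corrupted by additive noise:

    BOLD(t) = beta * (r * h)(t) + baseline + noise(t).

Estimation inverts this model: grid search over `(x0, y0, sigma)` plus
bounded nonlinear refinement, with `beta` and `baseline` solved linearly.
Because every analysis tool assumes its own HRF, size estimates inherit a
systematic bias from HRF-width mismatch; `prfval` exists to measure such
biases with known ground truth. The package provides

- **synthesis**: bar-sweep and randomized stimulus apertures on a calibrated
  visual-field grid; Gaussian and difference-of-Gaussians receptive fields;
  two-Gamma and Boynton HRF families; white + cardiac + respiratory + drift
  noise with calibrated low/mid/high presets; batch datasets with
  ground-truth tables and BIDS/NIfTI output;
- **a reference estimator**: `prf_fit()` fits the circular Gaussian linear
  model and returns an S3 object with `print`, `summary`, `coef`,
  `predict`, `fitted`, `residuals`, `plot` and `simulate` methods, plus
  median-of-seeds aggregation for outlier suppression;
- **reporting**: truth-vs-estimate error tables, trimmed summaries, 90%
  center-coverage ellipses and HRF-mismatch bias matrices;
- **calibration**: the on/off block-design procedure (coherence, cycle
  sinusoid fit, three-stage voxel selection) for estimating realistic noise
  levels;
- **orchestration**: `run_validation()` drives synthesize → fit → report
  from one JSON-serializable configuration (a thin CLI wrapper lives at
  `inst/cli/prfval.R`).

## Worked example

```r
library(prfval)

stim <- default_stimulus()                     # 101 x 101 x 200, 20 deg field
truth <- gaussian_prf(3, 3, 2)                 # center (3, 3) deg, sigma 2 deg
vox <- synthesize_voxel(truth, stim, hrf_two_gamma(),
                        noise = noise_preset("mid"), seed = 1)
fit <- prf_fit(vox$bold, stim, hrf_two_gamma())
fit
#> Circular Gaussian pRF fit
#>   center (x0, y0): (3.233, 3.181) deg
#>   size (sigma):    2.170 deg
#>   gain 1.059, baseline 0.0343
#>   rmse 4.381, variance explained 0.427
```

Even at mid-level noise (about −0.5 dB for a single acquisition) the
estimator returns the generating parameters to within a few tenths of a
degree; `varexp` reports the fraction of series variance the fit explains.
The HRF-mismatch experiment is two more lines:

```r
hrfs <- default_hrf_set()                      # four width-ordered HRFs
sapply(hrfs, function(h)
  prf_fit(synthesize_voxel(truth, stim, h)$bold, stim, hrfs[[2]])$sigma)
#> boynton-narrow boynton-medium   boynton-wide  boynton-broad
#>       1.539033       2.000000       2.699340       3.813443
```

Synthesizing with a narrower HRF than the analysis assumes shrinks the
estimated pRF radius; a wider one inflates it — only the matched condition
recovers sigma = 2.

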