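# adapts — adaptive model-switching T2* estimation from magnitude MR images

Region-of-interest (ROI) T2* estimation for cardiac and liver iron-load
quantification from multi-echo gradient-echo magnitude images, with a
per-ROI uncertainty estimate.  The package is aimed at offline,
vendor-independent analysis: the only required inputs are the magnitude
images, their echo times and an ROI.

## The method

Magnitude MR images have a positive noise floor (Rician for one coil,
noncentral chi for a root-sum-of-squares multi-coil reconstruction), which
biases naive exponential fits of `S(TE) = PD·exp(−TE/T2*)` upward, worst at
short T2* (heavy iron load).  The estimator balances accuracy and
precision by switching models:

1. **Pre-fit** of a three-parameter offset model
   `S = PD·exp(−TE/T2*) + C` (C approximates the noise floor), initialised
   by weighted least squares on the signal logarithm (WLSL, weights `S²`).
2. **Truncation**: echoes with `TE > P1 · T2*^` are excluded
   (`P1 = 4.5`), where `T2*^` is the pre-fit estimate.
3. **Switch**: if at least `P2 = 9` echoes survive, T2* is re-estimated by
   a two-parameter monoexponential fit on the retained echoes; otherwise a
   three-parameter second-moment noise-corrected fit
   `M ≈ sqrt((PD·exp(−TE/T2*))² + k)`, with `k = 2Lσ²` free, is applied to
   all echoes.

The ROI uncertainty comes from T2* estimates over non-overlapping
subregions (4 % of the ROI each): the ensemble SD is corrected by
`sqrt(n/N)` for the smaller averaging size, and reported as a 95 % CI size
(`3.92·SD`) and coefficient of variation (CoV).  A multi-coil magnitude
noise simulator and seeded Monte-Carlo runners reproduce the estimator's
accuracy, precision and CI-coverage characteristics; see the vignette
(`vignettes/t2star-estimation.Rmd`) for the models, assumptions and design
choices.

## Worked example

```r
library(adapts)

set.seed(7)
noise <- coil_noise_model(n_coils = 6, sigma = 100 / 15)   # SNR = 15
roi <- simulate_roi_pixels(t2 = 8, s0 = 100, noise, liver_protocol(),
                           roi_pixels = 100)

sig <- decay_signal(liver_protocol(), rowMeans(roi$pixel_signals))
adapts_estimate(sig)
#> <adapts_result> T2* = 8.344 ms (truncation branch)
#>   initial T2* (offset pre-fit): 7.502 ms; echoes retained by truncation: 10

estimate_uncertainty(roi, fraction = 0.04)
#> <uncertainty_result> ROI T2* = 8.344 ms
#>   corrected SD = 0.030 ms; 95% CI size = 0.117 ms; CoV = 0.004
#>   25 subregions of 4 pixels (0 excluded)
```

The simulated ROI has a true T2* of 8 ms at SNR 15 with a 6-coil RSS
reconstruction; the estimate lands within a few percent, the pre-fit
threshold (4.5 × 7.5 ≈ 34 ms) retains all ten echoes, so the truncated
two-parameter branch is used, and the subregion ensemble yields a small CI
and CoV, as expected for a homogeneous 100-pixel ROI.

Image data go through the readers instead: `read_multiecho_dicom()`
(single-frame magnitude series), `read_multiecho_nifti()` (volume + TE
sidecar in ms) or `read_signal_table()` (plain CSV), then
`fit_roi(stack, roi_spec(...), with_uncertainty = TRUE)`, which also
raises an advisory when the CoV suggests reviewing the ROI delineation.
A command-line front end is in `inst/cli/adapts.R`
(`fit` / `simulate` / `validate`).

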