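---
title: "Adaptive model-switching T2* estimation: models, algorithm and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive model-switching T2* estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adapts)
```

## The measurement problem

Tissue iron shortens the effective transverse relaxation time T2* of the MR
signal, so T2* mapping from multi-echo gradient-echo (mGRE) magnitude images
is the standard non-invasive measure of cardiac and hepatic iron load.  The
physics is a monoexponential decay sampled at the echo times TE:

$$S(\mathrm{TE}) = PD\, e^{-\mathrm{TE}/T_2^*},$$

with proton density $PD$ the signal at TE = 0.  Clinically relevant T2*
spans roughly 1--50 ms, while the echo trains are fixed by the sequence
(here 2.5--25 ms for the cardiac protocol and 1.3--20.1 ms for the liver
protocol, ten echoes each).  Two regimes are therefore hard:

* **Short T2*** (heavy iron load): the decay dies within the first echoes
  and the remaining samples sit on the *noise floor* -- magnitude images
  have strictly positive noise (Rician for one coil; noncentral chi for a
  root-sum-of-squares, RSS, multi-coil reconstruction), so the signal
  plateaus instead of reaching zero.  An unmodelled floor biases T2*
  upward.
* **Long T2*** relative to the echo train: little decay is observed and
  precision degrades; every additional free parameter makes it worse.

No single model is best across both regimes, which is why this package
switches between them.

## The three signal models

1. **Monoexponential** (`monoexp`): $S = PD\,e^{-TE/T_2^*}$, two
   parameters.  Best precision, but biased by the noise floor unless
   floor-dominated echoes are removed.
2. **Offset model** (`offset`): $S = PD\,e^{-TE/T_2^*} + C$, with $C \ge 0$
   approximating the noise plateau.  Flexible, but the third parameter
   makes it noise-sensitive, so it is used only as a *pre-fit*.
3. **Second-moment noise-corrected model** (`second_moment`): for an RSS
   combination of $L$ coils with per-channel Gaussian noise SD $\sigma$,
   the second moment of the measured magnitude $M$ obeys
   $E[M^2] = S^2 + 2L\sigma^2$ exactly.  The model predicts the measured
   magnitude as $\sqrt{S^2 + k}$ with the noise term $k = 2L\sigma^2$
   fitted as one free parameter, so no separate noise measurement is
   needed.  Residuals are kept in the magnitude domain: fitting squared
   signals instead would concentrate the weight on the earliest echoes and
   visibly degrade precision at long T2*.

All nonlinear fits minimise unweighted least squares with a Nelder--Mead
simplex (single start, standard reflection/expansion/contraction
coefficients 1, 2, 0.5, 0.5, relative tolerance $10^{-8}$ on both the
vertex spread and the objective, at most 2000 iterations).  Box
constraints -- $PD, C, k \ge 0$ and $0 < T_2^* \le 10\,\max(TE)$ -- are
enforced by a violation-scaled penalty; the upper clamp keeps the
truncation step well-defined on pathological inputs (an ROI with no
visible decay pins the estimate at the ceiling, which downstream reporting
flags explicitly).  Fits are initialised by weighted least squares on the
signal logarithm (WLSL): regression of $\log S$ on TE with the standard
variance-stabilising weights $S^2$, giving $PD = e^{\text{intercept}}$ and
$T_2^* = -1/\text{slope}$ in closed form.  For the offset pre-fit the
decay part is initialised by WLSL on the *offset-subtracted* series
($S - \min S$, clamped positive): on floor-dominated signals raw WLSL sees
a nearly flat series and would start the simplex in a spurious large-T2*
basin.

## The switching algorithm

`adapts_estimate()` implements the adaptive estimator on one ROI-averaged
signal:

1. Fit the offset model to all echoes; its decay constant
   $\hat T_2^*$ is used **only** for truncation.
2. Exclude echoes with $TE > P_1 \hat T_2^*$ (the boundary is inclusive:
   only echoes strictly exceeding the threshold are dropped).
3. If at least $P_2$ echoes remain, re-estimate T2* by a two-parameter
   monoexponential fit on the retained echoes (*truncation branch*);
   otherwise fall back to the three-parameter second-moment fit on **all**
   echoes (*noise-corrected branch*).

The defaults $P_1 = 4.5$ and $P_2 = 9$ are the optimised values for
ten-echo clinical protocols; the parameter-sweep experiment
(`run_parameter_sweep()`) reproduces the robustness plateau above
$P_1 \approx 3$.  For the cardiac train the switch sits at
$\hat T_2^* = 22.5/4.5 = 5$ ms.  A pre-fit that stops at the iteration cap
still carries its best vertex, which truncation uses as-is; forcing
"keep all echoes" on non-convergence instead would route floor-dominated
short-T2* signals into the truncation branch and inflate both bias and CI
there.

## Subregion uncertainty

ROI-based estimation yields one number per ROI and no spread.  To attach a
precision estimate, the ROI is partitioned into non-overlapping subregions
of $n = \max(2, \mathrm{round}(0.04\,N))$ of its $N$ pixels (contiguous
chunks in the stable pixel order -- deterministic, and approximately
spatially contiguous for compact ROIs), T2* is estimated per subregion,
and the ensemble SD is corrected for the smaller averaging size: the
subregion pixel mean has a $\sqrt{N/n}$-times larger standard error, so

$$\hat\sigma_{T_2^*} = \sqrt{n/N}\; \mathrm{SD}(T_2^{*\,\text{subregions}}),$$

assuming statistically independent pixels and locally linear error
propagation.  The reported 95% CI size is the normal-theory
$2 \times 1.96\,\hat\sigma_{T_2^*}$ -- parametric rather than percentile,
because the ensembles are small (about 20--25 values) -- and the
coefficient of variation is $\hat\sigma_{T_2^*} / T_2^{*\,\text{ROI}}$.
The 4% subregion fraction is the validated default: smaller subregions
give more ensemble members and consistently better CI-estimate precision,
which `run_subregion_optimization()` demonstrates.  Remainder pixels that
do not fill a subregion are excluded from the ensemble only, never from
the full-ROI fit.

## The simulator

`simulate_pixel()` mirrors the physics of an RSS reconstruction: every
coil carries the identical decay $s_0 e^{-TE/T_2^*}$ on both its real and
imaginary component, independent $N(0, \sigma^2)$ noise is added per
component, and channel magnitudes combine as
$\mathrm{RSS} = \sqrt{\sum_l M_l^2}$.  SNR is defined as $s_0/\sigma$ on
the per-channel amplitude.  Under this convention the noise floor relative
to the TE = 0 signal is nearly constant in the coil count
($\approx (1 - 1/8L)\,/\,\mathrm{SNR}$), which is what makes accuracy
curves comparable across 1-, 6- and 32-coil reconstructions, while
precision still improves with $L$; normalising the per-channel amplitude
by $\sqrt{2L}$ instead would make the floor grow like $\sqrt{L}$ and the
32-coil bias explode.  This amplitude convention is the one substantive
free choice in the simulator and is the package's design decision.  The
overall scale $s_0 = 100$ is immaterial because every estimator is
scale-invariant (a tested property).

What the generator deliberately does **not** emulate: spatially varying or
correlated noise (parallel-imaging g-factor structure), motion, fat
signal, B0-induced non-exponential decay, or T2* heterogeneity within the
ROI.  Passing validation therefore demonstrates correctness of the
estimator under the stated noise model, not robustness to those real-data
effects.

For ROI work, `simulate_roi_pixels()` draws independent pixels and the
estimators consume their per-echo mean ("the ROI average"), except the
true-sigma comparator `m2ncm_fit()`, which consumes the per-echo root
mean square: $E[\overline{M^2}] = S^2 + 2L\sigma^2$ holds exactly for the
mean of squares, making the comparator nearly unbiased, with its small
residual bias -- the gap between $E[M]$ and $\sqrt{E[M^2]}$ -- largest for
a single coil.

## Monte-Carlo experiments and problem sizes

The four experiment runners are seeded and deterministic (each grid cell
derives its own RNG stream from the base seed, so cells are reproducible
in isolation):

* `run_accuracy_precision_sweep()`: mean bias and 95% CI (2.5--97.5
  percentile span of the repetition ensemble) per true T2* and coil
  count, for the switching estimator, the true-sigma comparator and the
  two component models applied unconditionally.
* `run_ci_validation()`: per-ROI subregion CI estimates against the
  reference CI of repeated full-ROI estimates, including the
  coverage flag (reference inside the 2.5--97.5% limits of the estimate
  ensemble).
* `run_parameter_sweep()` and `run_subregion_optimization()`: the
  $(P_1, P_2)$ and (ROI size, subregion fraction) grids.

Default T2* grids cover the simulated ranges at 1-ms spacing (2.2 then
3--50 ms cardiac, 1--50 ms liver; values below the shortest TE are not
simulated).  The default repetition count is 2000 per cell, the size used
by `scripts/acceptance.R`; the test suite runs the same experiments at 500
repetitions with correspondingly widened Monte-Carlo tolerances to stay
desk-scale.  The CI-validation grids use four representative T2* values
per protocol (2/3, 5, 10, 20 ms) spanning the heavy-overload to normal
range.

## Known limitations

* Just above the branch switch the truncation branch retains 9--10 echoes
  whose tail sits in the noise floor; the resulting overestimation peaks
  there (about half a millisecond at SNR 15 for the liver train) and
  decays with increasing T2*.  This is the documented cost of the
  precision-preserving $P_2$ rule, and the accuracy sweep reproduces it.
* The $\sqrt{n/N}$ correction assumes independent pixels; spatially
  correlated noise (e.g. from parallel imaging) breaks the assumption and
  the CI estimate will be optimistic.
* An ROI with no visible decay (background, pure noise) pins the estimate
  at the T2* clamp ceiling; `fit_roi()` raises the delineation advisory in
  that case because the CoV alone can look deceptively small when all
  subregions clamp alike.
* The DICOM reader covers uncompressed little-endian single-frame
  magnitude series only; enhanced multi-frame dialects are out of scope,
  and NIfTI input expects the TE sidecar in milliseconds.
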