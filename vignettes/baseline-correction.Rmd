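---
title: "Optimized and learned parameter selection for airPLS baseline correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimized and learned parameter selection for airPLS baseline correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airplsopt)
library(dplyr)
```

## The problem

Raman and SERS spectra sit on a slowly varying background — fluorescence,
substrate scattering — that must be estimated and subtracted before peaks
can be quantified. airPLS (adaptive iteratively reweighted penalized least
squares) is the workhorse: it alternates a Whittaker smooth

$$ (W + \lambda D_p^\top D_p)\, z = W y $$

with adaptive downweighting of channels that sit above the current
baseline $z$. Three parameters govern it: the smoothness weight
$\lambda$, the convergence tolerance $\tau$, and the difference order
$p$. In practice nearly everyone runs the defaults
$(\lambda, \tau, p) = (100, 10^{-3}, 1)$, and on many spectral shapes
those defaults are poor — the error can be an order of magnitude or two
above what tuned parameters achieve, and the first-order penalty yields
visibly rough baselines.

This package implements a three-part answer:

1. **A fast, overflow-safe airPLS kernel** (`airpls()`,
   `whittaker_smooth()`): a banded Cholesky solve, $O(n)$ in the number
   of channels, with the reweighting
   $w_i = \exp(t\,|d_i|/m)$ for negative residuals $d_i$ (where $m$ is the
   negative-residual mass and $t$ the iteration), $w_i = 0$ elsewhere,
   and endpoints anchored at the maximum weight. Iteration stops when
   $m < \tau \sum_i |y_i|$.
2. **A per-spectrum optimizer** (`optimize_spectrum()`,
   `optimize_dataset()`): an adaptive grid search over
   $(\log_{10}\lambda, \log_{10}\tau)$ with $p = 2$ that minimizes the
   mean absolute error (MAE) between the fitted and a *known* true
   baseline — usable on synthetic or reference data only, where truth
   exists.
3. **A parameter predictor** (`train_param_predictor()`,
   `predict_params()`): PCA of the training spectra followed by two
   100-tree random forests that map a raw spectrum directly to
   near-optimal $(\lambda, \tau)$, so tuned performance carries over to
   spectra without known baselines, at milliseconds per spectrum.

Performance is scored as percentage improvement over the default fit,
$\mathrm{PI} = (\mathrm{MAE_{DP}} - \mathrm{MAE_{new}})/\mathrm{MAE_{DP}}
\times 100$: 90 means one order of magnitude lower error, 99 two orders,
negative values mean the tuned/predicted fit is *worse* than the
defaults. We use the signed form throughout because the predictor can
genuinely degrade on noisy inputs, and the outlier rule
(`is_outlier_prediction()`) depends on that sign.

## The synthetic study design

All development and testing rests on a generator
(`generate_spectrum()`, `generate_dataset()`) that emulates a simulated
SERS study: three peak families — **B**road, **C**onvoluted,
**D**istinct — crossed with four baseline families — **E**xponential,
**G**aussian, fifth-order **P**olynomial, **S**igmoidal — giving 12
labeled shapes (`"B&E"` … `"D&S"`), plus compound shapes (equal-weight
baseline sums E+P, E+G, E+S, G+S and the compound peak B+C) for
robustness checks. Each spectrum carries its exact decomposition
(`intensity = true_signal + true_baseline`), so MAE against truth is
well defined. Gaussian noise is added at controlled SNR
(`add_noise()`), defined as `max(true_signal) / sd(noise)` — a common
spectroscopy convention; ten log-spaced levels span 6.47–49.92
(`snr_levels()`), the range observed in real bio-detection data.

Concrete generator choices (each a named default, swappable):

* Grid: 400–2000 cm⁻¹, 1024 uniform points — covering the fingerprint
  regions where tuning matters most.
* B peaks: 2–3 Gaussians, FWHM 4–8% of the span (64–128 cm⁻¹),
  separated by at least 1.8 FWHM, on a 100× intensity scale relative to
  C/D — broad-peak spectra in practice have much larger intensity
  scales, and this reproduces the two-orders-of-magnitude contrast in
  default-fit MAE between the families.
* C peaks: 6–12 equal-width Gaussians (FWHM 2–5% of span) chained at
  0.5–1.4 FWHM spacing, so the envelope never resolves.
* D peaks: 5–10 narrow Gaussians (1–3% of span) spaced more than 3× the
  widest FWHM.
* Baselines stay nonnegative with amplitudes comparable to the peak
  scale; the polynomial's coefficients decay as $1/(1+j)^2$ and the
  sigmoid steepness is 4–10 per span. These ranges were calibrated once
  so that a *tuned* airPLS fit can in fact recover the baseline to a few
  percent — with much wider broad peaks or near-step sigmoids the
  separation problem becomes ill-posed for any $(\lambda, \tau)$, which
  contradicts the regime this method family operates in.

What the generator does **not** emulate: Lorentzian/Voigt line shapes,
cosmic-ray spikes, detector response, wavelength-dependent noise, or
correlated (1/f) background drift. Passing tests on this generator
therefore show that the optimizer and predictor work where baselines are
smooth additive curves of the four stated families; they do not
establish performance on arbitrary measured spectra — the cosine
similarity of a new spectrum to the training library is the practical
applicability check.

## The optimizer

`optimize_spectrum()` works in $(\log_{10}\lambda, \log_{10}\tau)$ over
$\lambda \in [10^0, 10^{10}]$, $\tau \in [10^{-10}, 10^{-1}]$, with $p$
fixed at 2 (second-order smoothness; $\lambda$ and $\tau$ are then tuned
jointly because a $p$ change alone makes the default fit worse). The MAE
landscape over that plane is multimodal with a long diagonal valley, so
the opening move evaluates a dense 9×7 grid over the full bounds *plus*
a 5×5 grid centred on the initial pair; each subsequent refinement
re-centres a 5×5 grid on the incumbent best and halves the span.
Convergence: best MAE changing by less than 5% (relative to the previous
refinement's best) for 5 consecutive refinements, hard-capped at 50.
Ties break toward smaller $\lambda$, then smaller $\tau$. The reported
`refinements` count the *productive* refinements — up to the last one
that still moved the best MAE by more than the 5% tolerance — while
`total_refinements` includes the confirmation tail; productive counts
average about 3–4 on generator spectra.

Within a shape group, `optimize_dataset()` chains warm starts: each
search after the first initializes at the previous spectrum's optimum.
Because the full-bounds sweep always runs, the warm start's benefit here
is a finer opening grid around the shape's parameter cluster — it buys
accuracy at equal cost rather than fewer refinements.

Two numerical safeguards in the kernel matter for the search: the
reweighting exponent is clipped at 700 before `exp()`, and the
negative-residual mass is floored at machine epsilon times the
spectrum's total mass, so extreme $(\lambda, \tau)$ corners return
finite (if poor) fits instead of overflowing. Fits that hit `max_iter`
(default 100) return `converged = FALSE` rather than erroring, which
keeps batch optimization robust.

### The fractured small-$\lambda$ regime and robust labels

A structural finding that shaped the design: at the small-$\lambda$ end
of the valley the MAE surface is *fractured* — adjacent parameter pairs
a few hundredths of a decade apart can differ by three orders of
magnitude in MAE, because the iteration dynamics (exponentially
sharpening weights) bifurcate. The strict argmin often sits exactly
there. Such labels are unlearnable for any regression model: no
predictor can hit a razor edge. `optimize_spectrum()` therefore also
reports a *robust label*: among all pairs evaluated during the search
whose MAE is within 2.5× of the best, the one with the largest
$\lambda$ (then largest $\tau$) — the smooth end of the valley. The
strict argmin still defines the optimizer's own metrics
(`mae_op`, `pi`); the robust label is what the ML stage trains on.

## The predictor

`train_param_predictor()` normalizes each training spectrum to unit
maximum — airPLS is exactly scale-equivariant, so the optimal
parameters are scale-invariant and the 100× intensity spread between
peak families carries no target information — then projects onto the
principal components explaining 99.5% of variance (capped at 50) and
fits two 100-tree random forests. The $\lambda$ forest predicts
$\log_{10}\lambda$ directly; the $\tau$ forest predicts the *residual*
of $\log_{10}\tau$ around the straight line fitted to the training
optima in log-log space, so that predictions land on the diagonal
valley rather than scattering off it. Forest settings (`mtry` equal to
the number of retained components, i.e. bagged trees; node size 5) were
chosen by comparing validation-split PI across a small configuration
grid; the test split was evaluated once, after selection. Predicted
$\tau$ is clamped into $(10^{-12}, 0.5)$.

`evaluate_predictor()` scores predictions by fitting at the predicted
pair ($p = 2$) and comparing with the default fit; predictions with
negative PI or MAE above 10× the spectrum's grid-searched optimum are
flagged as outliers, reported both ways.

At the package's reduced study scale (50 spectra per shape, 40/5/5
split) the test-split success rate Pct(PI ≥ 70%) is about 75–85%
depending on the draw, with failures concentrated in the broad-peak
shapes; after outlier removal the mean PI is near 90%. On noisy spectra
the predictor degrades sharply — at SNR 49.92 the median PI is strongly
negative — and Savitzky–Golay denoising (window 15, order 2,
`savgol_denoise()`) recovers part of it, raising the estimated SNR
above 100. That ordering (noisy < denoised, both possibly negative) is
the property the package asserts; it mirrors the behavior of this
method family on measured spectra.

## Tunable parameters at a glance

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `lambda` | `airpls()` | 100 | smoothness weight; larger ⇒ smoother baseline (dimensionless) |
| `tau` | `airpls()` | 1e-3 | stop when negative-residual mass < `tau`·Σ\|y\| |
| `p` | `airpls()` | 1 | difference order of the penalty (2 in optimized mode) |
| `max_iter` | `airpls()` | 100 | iteration cap; exceeded ⇒ `converged = FALSE` |
| `lam_bounds`, `tau_bounds` | `grid_search_config()` | [0,10], [−10,−1] | log₁₀ search box |
| `open_shape`, `grid_shape` | `grid_search_config()` | (9,7), 5 | opening-sweep and refinement grid sizes |
| `shrink_factor` | `grid_search_config()` | 0.5 | per-refinement span contraction |
| `improvement_tol`, `patience` | `grid_search_config()` | 0.05, 5 | convergence rule |
| `robust_window` | `grid_search_config()` | 2.5 | MAE multiple defining the robust-label candidate set |
| `pca_var`, `max_components` | `train_param_predictor()` | 0.995, 50 | retained PCA dimension |
| `num_trees`, `mtry`, `nodesize` | `train_param_predictor()` | 100, all, 5 | forest geometry |
| `window_length`, `poly_order` | `savgol_denoise()` | 15, 2 | denoising filter |

## Numerical and degenerate-input behavior

* All-nonnegative weights with at least one positive entry are required
  by the solver; if reweighting drives the weighted channel count below
  the penalty's null-space dimension, the fit stops at the previous
  iterate (the endpoint anchoring makes this rare).
* A constant spectrum is its own baseline at any parameters; a zero
  reference MAE makes PI degenerate and is reported as 0 with a warning.
* Non-finite intensities error immediately; non-finite grid MAEs are
  discarded with a warning inside the search rather than aborting it.
* The SNR estimator (`estimate_snr()`) is a package definition (the
  field has no standard one): noise from second differences
  (`sd(diff(y, 2))/sqrt(6)`, which annihilates smooth structure), signal
  amplitude from a Savitzky–Golay smooth minus a coarse airPLS baseline;
  nearly noise-free spectra cap at 1e6. It tracks constructed SNR within
  ~25% (median) across the 6.47–49.92 range.
* Wavenumber spacing is assumed uniform; non-uniform grids are accepted
  but the difference penalty ignores spacing.

## Problem sizes used in the shipped checks

The package's own test suite and `scripts/acceptance.R` re-derive the
headline numbers at a reduced scale chosen to keep a full run on one
CPU comfortably inside an interactive session: 3 spectra per shape (36
grid searches) for the optimizer statistics and parameter-region fit,
and 50 per shape (600 searches, 40/5/5 split) for the ML stage, with the
compound suite (12 single draws) and the SNR-49.92 noise comparison on
the test split. At this scale the optimizer's overall mean PI is ~96–98%
with every shape above 90%, the parameter-region slope is positive
(≈0.8–0.9), and the ML stage behaves as described above.

## Known limitations

* Single random draws of S- or P-heavy compound shapes fail
  (PI < 50) in roughly 10–15% of draws through the fracture mechanism —
  the same mechanism behind the ~10% outlier rate on in-distribution
  test spectra. Averages are stable; individual draws are not.
* Optimization outcomes are chaotically sensitive: changing an input
  intensity by one floating-point ulp can move an individual spectrum's
  $(\lambda^*, \tau^*)$ substantially (aggregate statistics are
  unaffected). Results are bit-reproducible for a fixed build, but not
  across compilers or BLAS implementations.
* The optimizer requires a known true baseline by construction; on real
  spectra only the predictor applies, and only after denoising to
  SNR ≳ 100, and only for spectra resembling the training library
  (check with `cosine_similarity()`).
* $p > 2$, non-Gaussian line shapes, and alternative regressors
  (boosting, neural networks) are out of scope; the trainer's surface
  accepts them in principle but none are implemented.
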