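---
title: "Estimating leaf potassium from reflectance spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf potassium from reflectance spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracspec)
```

## The problem

Leaf potassium content is a workhorse indicator of plant physiological
status, but wet-chemistry determination is slow and destructive. Field
spectroscopy offers a fast alternative: potassium influences water balance,
cell structure and enzymatic activity, all of which leave weak, distributed
imprints on the 400--2500 nm leaf reflectance curve, concentrated in the
700--1100 nm and 1400--1800 nm regions. Two obstacles stand between a raw
spectrum and a usable potassium estimate:

1. the potassium signal is faint and buried under smooth, sample-specific
   baseline variation (brightness, scattering, water content), and
2. a 2101-band spectrum measured on a few hundred samples is a textbook
   overfitting regime for flexible regressors.

`fracspec` implements a pipeline that addresses both: **fractional
differentiation** of the spectra suppresses smooth nuisance variation and
sharpens narrow absorption features, and **PLSR latent-variable extraction**
compresses the spectrum into a handful of supervised directions before a
machine-learning regressor sees it.

## Fractional differentiation

The discrete Grünwald--Letnikov derivative of order $v \ge 0$ of a signal
$x$ sampled on a uniform grid is

$$ (D^v x)_i \;=\; \sum_{m=0}^{i-1} w_m\, x_{i-m}, \qquad
   w_0 = 1,\quad w_m = w_{m-1}\,\frac{m-1-v}{m}, $$

an expanding-window weighted difference whose generalised binomial weights
interpolate continuously between the identity ($v=0$), the first difference
($v=1$, weights $1,-1$) and the second difference ($v=2$, weights
$1,-2,1$). Fractional orders retain a long, slowly decaying memory of
preceding bands, which is what lets them amplify narrow features without the
noise blow-up of integer-order differencing.

Numerical choices:

* **Step size** is one band index (1 nm on the working grid). Derivative
  values are therefore in per-band units; only relative magnitudes matter
  downstream (correlations, latent directions are scale-free per band).
* **Weights by recursion, not Gamma ratios.** The textbook form
  $w_m = (-1)^m \Gamma(v{+}1)/(m!\,\Gamma(v{-}m{+}1))$ hits Gamma poles at
  integer $v$ for $m > v$; the multiplicative recursion is pole-safe and
  yields exact zeros there. The test suite checks agreement with the direct
  Gamma form to $10^{-12}$ wherever the latter is defined.
* **Expanding window, no truncation**: position $i$ uses all $i$ available
  history points back to the first band. This makes the discrete operator
  compose exactly: $D^a D^b = D^{a+b}$ (the weight sequences convolve as
  $(1-z)^a (1-z)^b = (1-z)^{a+b}$), a property the tests verify.
* **Boundary handling**: all output positions are returned, so the full
  400--2500 nm axis is preserved; early bands simply have short history. An
  optional `trim` argument drops leading bands for users who prefer a
  conservative margin.
* Orders are restricted to $[0, 3]$ (the analysis sweep is 0 to 3 in 0.1
  steps); negative orders (fractional integration) are rejected.

## PLSR and the cumulative-variance rule

The latent model is PLS1 fitted by NIPALS: each component's weight vector is
proportional to the residual cross-covariance $X_{res}^\top y_{res}$ on
centred data; scores are mutually orthogonal; $X$ and $y$ are deflated after
each component; predictions are $\hat q = \bar q + \sum_m f_m a_m$. At full
rank the fit coincides with ordinary least squares (tested against an OLS
oracle), and the implementation is cross-checked against an independent PLS
implementation on a small fixture.

Two component-selection rules coexist deliberately:

* **Standalone PLSR**: exhaustive search over 1--20 components scored by
  10-fold cross-validated $R^2$, ties toward fewer components.
* **Fusion front-end**: sequential extraction stops once the **cumulative
  explained predictor variance reaches 75%** (cap 30). We interpret
  "explained variance" as variance of the centred $X$ — the convention of
  PLS software and the natural reading when extraction serves dimensionality
  reduction; whether the rule could instead refer to $y$-variance is an open
  interpretation, and the threshold is a plain argument (`threshold`) so
  either convention's sensitivity can be probed.

$X$ is column-centred but not variance-scaled by default: differentiated
spectra carry meaningful relative band magnitudes, and unit-scaling would
promote noise-only bands. Scaling is available as a switch (`scale = TRUE`).
Zero-variance bands yield undefined correlations and are reported as `NA`,
never imputed as 0, and are excluded from per-order maxima of the
correlation surface.

## Fusion models and tuning

The three back ends are delegated to established implementations behind a
thin adapter: ranger (random forest), xgboost (gradient-boosted trees) and
nnet (feed-forward network). The adapters pin every source of randomness to
a derived seed and a single thread, so a fitted pipeline is reproducible
bit-for-bit.

* The random-forest grid unions the two tree-count schedules in common use
  (50--200 in steps of 50, and 100/200/300); both are also available as
  named presets. `mtry` candidates are `sqrt`, `log2` and 10.
* The boosted-tree grid covers learning rate 0.01/0.05/0.1, depth 3/5/7 and
  100--300 rounds.
* The network adapter standardises inputs and response by training
  statistics and fits a **single-hidden-layer** network (logistic
  activation, BFGS, L2 decay candidates $10^{-4}/10^{-3}/10^{-2}$, max 2000
  iterations, no early stopping). No installed R back end provides a
  multi-layer ReLU/Adam regressor, so the hidden-size candidates are the
  single-layer sizes 100 and 50; the pipeline properties tested here
  (dimensionality-reduction benefit, leak-freedom, determinism) do not
  depend on the specific architecture.

Grid search maximises mean K-fold cross-validated $R^2$ (each held-out fold
scored against its own mean), K = 10 by default, seeded shuffled folds, no
stratification (continuous target). Ties break by grid enumeration order
(first grid dimension varies fastest), which makes selection deterministic.
A single-cell grid skips cross-validation outright.

## The experiment harness

`run_experiment()` fixes **one** train/validation split (4/5 vs 1/5,
validation size `ceiling(n/5)`) before any transformation, and reuses it
across the whole order sweep and model grid: re-splitting per order would
confound order effects with split noise. For each order the spectra are
differentiated once; each model is fitted on the transformed training rows
only — latent extraction, grid search and refits never see validation rows
(an instrumentation test poisons the validation rows and verifies the
training-side artifacts are unchanged). Validation $R^2$ is computed against
the validation subset's own mean (conventions differ; this one is the
stricter). Best orders are selected on validation $R^2$ alone, ties toward
the lower order.

## The synthetic generator

The study data this pipeline is designed for are confidential, so the
package ships a generator that reproduces the *statistical structure* the
analysis assumes, making every stage testable end-to-end:

* **Potassium** follows a lognormal truncated to $[0.06, 5.87]$ (units of
  10 g/kg), with location/scale solved at configuration time from
  closed-form truncated moments so the truncated distribution has mean 0.81
  and coefficient of variation 1.30 — the field study's descriptive
  statistics. Draws use stratified inverse-CDF sampling by default (one draw
  per equal-probability stratum, randomly ordered): the marginal law is
  identical to i.i.d. sampling, but a 301-sample draw represents the
  calibrated moments to within a few hundredths instead of fluctuating with
  $\sigma/\sqrt{n} \approx 0.06$. Plain rejection sampling remains available
  (`stratify_k = FALSE`).
* **Reflectance** is a smooth continuum (base 0.12, red edge at 715 nm,
  SWIR decay) minus fixed water bands at 1450/1950 nm, minus Gaussian
  absorption features whose depth increases linearly with potassium, plus
  per-sample nuisance (amplitude jitter, baseline offset and tilt) and
  i.i.d. band noise (sd 0.004, an instrument-class figure; the study
  reports no per-band noise level, so this is a package choice). Feature
  depths are validated at construction so the noiseless spectrum stays in
  $[0, 1]$; stochastic spectra are clamped to $[0, 1]$ as reflectance is
  physically bounded.
* The **default preset** places three broad potassium-coupled features at
  760, 980 and 1650 nm — strong per-band signal, convenient for unit tests.
* The **derivative-sensitive preset** spreads the potassium coupling across
  32 narrow features (widths 6--12 nm) inside 700--1100 and 1400--1800 nm
  and adds smooth per-sample offset/tilt nuisance. At order 0 the nuisance
  masks the signal (band correlations $\approx 0.2$); differentiation
  annihilates the smooth nuisance and reveals the narrow features (band
  correlations $\approx 0.5$, deliberately of the same modest magnitude as
  published band--potassium correlations), so the order sweep has an
  interior optimum and latent-based fusion models outperform standalone
  regressors on raw bands — the qualitative behaviour the pipeline exists to
  exploit. This is a *construction*: passing the end-to-end tests shows the
  pipeline recovers a signal with this structure, not that real leaf spectra
  have it.

What the generator does **not** emulate: physically based radiative
transfer, species/plot hierarchies, wavelength-correlated noise (available
as an extension hook but off by default), and instrument artefacts such as
detector seams.

## Problem sizes used by the shipped tests

The full published protocol (31 orders, seven models, 10-fold tuning over
the complete grids) is an overnight computation. The shipped end-to-end test
runs the same code path at the sizes a desk check warrants: 301 samples,
orders 0 to 3 in 0.5 steps, 5-fold tuning, the `"reduced"` grids, a
single-cell grid and a very small network for the standalone baselines
(standalone networks on 2101 standardised bands are the slowest cell by two
orders of magnitude and their role in the comparison is only to be
out-performed). The byte-identity reproducibility check reruns a further
trimmed two-order experiment twice. All documented defaults remain the full
protocol.

## Known limitations

* The Grünwald--Letnikov operator assumes an exactly uniform grid; input on
  other grids is linearly resampled first, which smooths sub-nm structure.
* Early bands of a differentiated spectrum rest on short history; downstream
  statistics treat them like any other band unless `trim` is used.
* Validation-set $R^2$ on 61 held-out samples of a heavy-tailed response has
  substantial seed-to-seed variance; single-split rankings of closely
  matched models should not be over-read.
* The feed-forward back end is a single-hidden-layer network; see above.
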