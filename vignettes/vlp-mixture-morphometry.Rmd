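---
title: "Resolving virus-like particle sub-populations from AFM images with Gaussian mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving virus-like particle sub-populations from AFM images with Gaussian mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlpmix)
```

## The problem

Virus-like particles (VLPs) — self-assembled, DNA-free capsids used as
vaccine antigens — change shape as they age in solution. When a collection of
VLPs is imaged by atomic force microscopy (AFM) under a stiff, compressing
tip, the per-particle area (nm²) or lateral width (nm) distribution carries a
signature of that change: a homogeneous population gives a single normal
distribution, while stepwise morphological change gives a multimodal mixture.
A sample mean and standard deviation cannot distinguish these cases.
`vlpmix` implements the full analysis path: segmenting particles out of AFM
topographs, fitting univariate Gaussian mixture models (GMMs) by
Expectation–Maximization (EM), judging how many sub-populations the data
support, and comparing populations across aging conditions.

## The model

A `k`-component GMM has density

$$p(x) = \sum_{j=1}^{k} w_j\, G(x \mid \mu_j, \sigma_j), \qquad
\sum_j w_j = 1,$$

with $G$ the normal density, so $3k - 1$ free parameters. The fit maximizes
the log-likelihood $\ell(\theta) = \sum_i \log \sum_j w_j G(x_i \mid \mu_j,
\sigma_j)$ by EM: the E-step computes posterior membership probabilities
(responsibilities) $\gamma_{ij}$, the M-step re-estimates $(w_j, \mu_j,
\sigma_j)$ as responsibility-weighted moments. Each iteration cannot decrease
$\ell$, which is the central testable property of the implementation and is
asserted across every fit in the test suite.

Numerical choices:

* **Log-space arithmetic.** Component densities at nm²-scale observations
  underflow in linear space; all responsibilities and likelihoods use
  log-sum-exp normalization.
* **Convergence.** Successive log-likelihoods agreeing in absolute value
  within `tol = 1e-6` (the "six decimal places" reading), capped at 1000
  iterations; both the criterion that fired and the trace are returned.
* **Variance update.** The M-step variance uses the freshly updated mean
  $\hat\mu_j$ — the standard EM update, stated here explicitly because the
  update can also be read with the previous iteration's mean.
* **Sigma floor.** $\sigma_j \ge 10^{-6} \times \mathrm{range}(x)$ guards the
  well-known likelihood singularity of mixtures (a component collapsing onto
  one point with $\sigma \to 0$).
* **Initialization and restarts.** Means start on the $(j - 0.5)/k$ data
  quantiles with pooled-sd sigmas and uniform weights; ten additional starts
  perturb the quantile means, each is run for a 50-iteration burn-in, and the
  most promising start runs to convergence. On a 500-point two-component
  fixture this scheme reaches a higher optimum than a reference fitter's
  hierarchical-clustering start (asserted in the tests).
* **Canonical order.** Components are always reported sorted by ascending
  mean, so results are invariant to initialization order and directly
  comparable across runs.

## Goodness of fit and choosing `k`

The mixture QQ diagnostic sorts the data and pairs the $i$-th order statistic
with the model quantile at plotting position $(i - 0.5)/N$ — the midpoint
convention, consistent with reading a quantile as the fraction of
observations below a value. Model quantiles invert the mixture CDF by
bracketed bisection (tolerance $10^{-9}$ × scale, verified as a round-trip
inverse in the tests). A least-squares line through the pairs summarizes
linearity; under a correctly specified model the points concentrate on the
identity line and the coefficient of determination approaches 1.

`select_gmm()` makes the judgment call "an extra component no longer
significantly improves the fit" concrete: walking $k = 1, 2, \dots$, the
larger model is kept only if it gains at least `gain_threshold` (default 2.0,
roughly one AIC unit per extra parameter) in log-likelihood *and* at least
`linearity_threshold` (default 0.005) in QQ $R^2$, per added component. Both
thresholds are configurable; the defaults were calibrated once on the
simulator's presets so that 1000-point single-Gaussian samples select $k = 1$
and well-separated two-component samples select $k = 2$, and were then
frozen. Raising either threshold can only lower the selected $k$ (a tested
monotonicity property). `force_k` records a manual override, the escape
hatch for judging a visually better fit.

Component-mean confidence intervals use $\pm t\,\sigma_j/\sqrt{n}$ with the
effective per-component count $n = N/k$ rounded half up and $t$ the
two-sided Student quantile with $n - 1$ degrees of freedom. The half-up
rounding is deliberate: it reproduces the published per-component counts
(36/2 → 18, 33/3 → 11, 23/4 → 6, 19/2 → 10) and, with the published sigmas,
the printed half-widths 60, 51, 18, 46 and 3.7. One published half-width
(±120 for the 3-h component with σ = 185, n = 11) is not reproducible by
the formula, which gives 124; the package keeps the formula.

Conditions are compared by hard-assigning each particle to its
maximum-responsibility component (ties to the smaller mean) and applying
Pearson's chi-squared test (no continuity correction) to the condition ×
component count table. When each condition has its own model, components are
aligned across conditions by ascending-mean rank; a fixed-bin histogram
alternative can be built by passing a shared model. The construction of the
published count tables is not recorded, so this default is a documented
choice, not a reconstruction.

## The image chain

`extract_particles()` reimplements the described processing chain:

1. grayscale conversion (BT.601 luminance for color input);
2. Fourier bandpass (attenuate structures < 3 px and > 40 px — ImageJ's FFT bandpass
   defaults — with smooth Gaussian transfer functions; the
   mean is preserved and output is clipped to the 8-bit range rather than
   re-stretched, so flat inputs pass through unchanged);
3. Sobel 3×3 gradient magnitude (the behaviour of ImageJ's "Find
   Edges" routine);
4. thresholding of the edge map. The manual workflow adjusts this
   threshold by eye between 10 and 45 units to close as many particle
   contours as possible without fusing neighbours; `threshold_sweep()`
   automates exactly that criterion — it counts plausible particles (closed
   contour, off-border, size window, circularity ≥ 0.5) at each level and
   keeps the level maximizing the count, breaking ties toward the lowest
   level;
5. 8-connected component labeling (the default of ImageJ's Analyze
   Particles) with hole filling, so a closed edge ring becomes one
   solid particle, flagged `boundary_closed`; border-touching regions are
   kept but flagged and excluded from statistics;
6. calibrated measurement: `area_nm2 = area_px (200/c)²`,
   `width_nm = width_px (200/c)` at `c` pixels per 200 nm (defaults to 115,
   the midpoint of the reported 103–125 range; values outside it warn).

**Measurement convention.** A thresholded edge contour has finite thickness
(≈3 px for a Sobel ring after bandpass smoothing), and the filled ring
overstates the particle area by roughly half that annulus. `measure_particles()`
therefore reports the *contour-midline* estimate — the enclosed hole plus
half the ring, with width reduced by the mean ring thickness — and retains
the raw filled pixel count as `area_px_raw`. On simulated topographs this
estimator recovers the analytic particle area within a few percent where the
raw count is biased by +40–55%. Width is measured on the thresholded mask as
the widest lateral (x-axis) extent; the original manual on-screen width
measurement cannot be reproduced literally.

## The simulator

Because the raw measurement sets behind the published fits are not deposited,
the package ships the published fitted parameters as presets
(`gmm_presets()`), covering areas at 2/3/4 h, single- and double-pass widths,
and the pooled ensembles. `sample_mixture()` draws from any preset with the
latent component labels retained, so estimator accuracy can be judged against
known truth.

`make_afm_image()` renders particles as radially symmetric flat-topped domes
$I(r) = A\,2^{-(r/R)^p}$ (shape exponent $p = 8$) on a noisy background —
the silhouette of a capsid compressed by a stiff tip. The half-maximum
radius $R$ is the particle's nominal radius and $\pi R^2$ its analytic
reference area; a flat-top profile rather than a plain Gaussian dome is
deliberate, since a Gaussian has no defensible edge and makes "true area"
ill-posed for validating the chain. Default conditions: 256² px images at
115 px per 200 nm, radii 11–15 px (areas ≈ 1100–2100 nm², the reported VLP
area scale), peak contrast 160 above a background of 20, additive Gaussian
noise with sd 6 clipped to [0, 255]. Layouts are rejection-sampled so
particles stay off the border and apart; deliberately overlapping layouts are
allowed but flagged, emulating the contiguous-particle failure mode that
motivated the threshold balancing in the first place.

What the simulator does *not* emulate: tip–sample mechanics, tip-shape
convolution, scan-line artifacts, height information, or JPEG compression.
Passing tests therefore demonstrate the correctness of the measurement and
inference machinery on idealized topographs, not robustness to every
instrument artifact of real AFM data.

## Problem sizes and known limitations

The test and acceptance workloads use study-scale problems: fits at
N = 200–5000, selection at N = 1000, QQ contrasts at N = 500, and ten 256²
simulated topographs with five particles each.

Two limitations are worth stating plainly:

* For the pooled four-component area preset, the two central components
  (means 1479 and 1617 nm², sigmas 194 and 54) overlap heavily. At N = 5000
  the maximum-likelihood estimate itself — not merely this implementation —
  has enough sampling variance that a 2%-mean / 0.03-weight recovery check
  succeeds in only ~60% of random draws; EM restarted from the generating
  truth does no better, and an independent fitter does worse. Recovery of
  such configurations needs either more particles or external constraints.
* Model selection by log-likelihood-gain plus QQ-linearity thresholds is a
  calibrated heuristic, not a hypothesis test; information criteria or
  bootstrap tests are intentionally out of scope because the reproduced
  workflow did not use them.

## A worked run

```{r, eval = FALSE}
library(vlpmix)

# simulate a 2-h area collection, fit, and summarize
x <- sample_mixture(gmm_preset("area_2h"), n = 300, seed = 1)
sel <- select_gmm(x, k_range = 1:4, seed = 1)
tidy(sel)                    # per-k report
tidy(sel$model, conf_int = TRUE)
autoplot(sel$model)
autoplot(qq_diagnostic(x, sel$model))

# image route: render, extract, compare to truth
tr <- simulate_particle_truth(5, size = 256, seed = 3)
img <- make_afm_image(tr, seed = 3)
extract_particles(img, calibration = 115)
truth_measurements(tr)
```
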