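---
title: "Quadratic-variance preprocessing of SELDI-TOF spectra: model, method, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadratic-variance preprocessing of SELDI-TOF spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seldiprep)
```

## The problem

SELDI-TOF mass spectrometry produces low-resolution protein spectra whose
preprocessing — denoising, baseline removal, peak detection — largely
determines which proteins a downstream biomarker analysis ever sees. Most
preprocessing tools assume the detector noise has constant variance. It
does not: on repeated matrix-only ("buffer") acquisitions, the pointwise
intensity variance grows with the pointwise mean, and the relationship is
well approximated by a quadratic. `seldiprep` builds the whole
preprocessing chain on that observation.

## The detector model

At each point of the mass/time grid the observed intensity is modeled as
a draw from a natural exponential family with quadratic variance function
(NEF-QVF):

$$ V(\mu) \;=\; \upsilon_0 + \upsilon_1\,\mu + \upsilon_2\,\mu^2 . $$

The NEF-QVF class contains the normal ($\upsilon_1=\upsilon_2=0$),
Poisson ($\upsilon_0=\upsilon_2=0$) and gamma distributions among others,
and is closed under summation — relevant because an acquired spectrum is
itself a sum of single laser-shot spectra. The intercept $\upsilon_0$ is
naturally read as an electronic noise floor and the linear term as
compound-Poisson ion counting; the quadratic term is measured rather than
mechanistically derived.

The three coefficients are estimated from $n \ge 3$ replicate buffer
spectra: `pointwise_moments()` computes the per-grid-point sample mean
and unbiased sample variance across replicates, and `fit_qvf()` regresses
variance on (1, mean, mean²) by ordinary least squares. Design choices
here, made where the procedure is genuinely underdetermined:

* **OLS, not weighted.** A weighted variant (weights $\propto$
  1/variance², reflecting the size-dependent sampling error of sample
  variances) is available via `weighted = TRUE`, but the default is the
  minimal reading: an unweighted best-fit quadratic.
* **Every grid point is one fit point.** No binning of the
  (mean, variance) scatter.
* **Coefficients may individually be negative.** The fit is rejected
  only if the fitted $V$ is non-positive somewhere on the observed mean
  range, or if $1+\upsilon_2 \le 0$ (the denoiser divides by it).
* Estimation is restricted to the instrument's mass-focused window
  (3–30 kDa in the settings this package models); below ~2.5 kDa the
  detector saturates and the quadratic model is not expected to hold.

## Mean spectrum and wavelet shrinkage

For $n$ spectra from one homogeneous condition the pointwise mean
spectrum $\bar X(t)$ has expectation $\mu(t)$ and variance $V(\mu(t))/n$.
Peak detection runs once, on an estimate $\tilde\mu$ of $\mu$, rather
than per spectrum — which also removes the need for cross-spectrum peak
matching.

$\tilde\mu$ is obtained by shrinkage in an orthogonal wavelet basis
(Symmlet 8 by default):

$$ w = W\bar x, \qquad
   \tilde h(i) = \frac{[\,w(i)^2 - \tilde\sigma^2(i)\,]_+}{w(i)^2}, \qquad
   \tilde\mu = W'\,\mathrm{diag}(\tilde h)\,w , $$

with per-coefficient noise variances propagated exactly through the
squared transform matrix:

$$ \tilde\sigma^2 = \frac{1}{1+\upsilon_2}\,(W\cdot W)\,
   \frac{V^\dagger(\bar x)}{n}, \qquad
   V^\dagger(x) = \max\{V(x), \upsilon_0\} . $$

$(W\cdot W)$ is the matrix of squared entries of $W$; for independent
pointwise noise it maps pointwise variances to exact coefficient
variances, and orthogonality of $W$ makes each of its rows sum to 1, so
constant variance passes through unchanged. The clamp $V^\dagger$ keeps
low-signal regions from having their noise underestimated: where the
fitted quadratic dips toward zero, the noise floor $\upsilon_0$ takes
over.

Numerical and structural choices:

* **Periodized pyramid DWT.** Periodization is the boundary handling
  that keeps the finite transform exactly orthogonal ($W'W = I$ to
  ~1e-13, verified in the tests), which the variance propagation, the
  energy bound $\|\tilde\mu\|\le\|\bar x\|$, and the row-sum property all
  rest on. The transform matrix is built once per (length, basis, depth)
  by transforming the identity and cached; spectra of realistic lengths
  (2¹⁰–2¹³) make this a few-second, few-hundred-MB one-off cost.
* **Non-dyadic lengths** are symmetric-reflection padded to the next
  power of two, denoised, and cropped. The variance vector is padded the
  same way, so the operator actually applied retains the row-sum
  property. No interpolation or resampling ever happens.
* **Decomposition depth** defaults to the number of halvings for which
  the working length still covers the filter (10 levels for a 8192-point
  sym8 transform).
* **$\tilde h(i) := 0$ when $w(i)=0$** — the limit of the formula, and
  inconsequential since the coefficient carries nothing.
* **No cycle spinning.** The plain orthogonal transform is the method;
  translation-invariant averaging would change its statistics.
* **The replicate count $n$ is an explicit argument** of
  `sigma2_tilde()`/`shrink_spectrum()` with default 1. $n=1$ treats the
  input as a single raw spectrum — equivalently, it applies $V(\bar x)$
  undivided, the more aggressive smoothing. The pipeline driver passes
  the true $n$ of the averaged group, because $V(\mu)/n$ is the actual
  noise variance of a mean spectrum and using it preserves the estimator's
  risk properties at the scale of the data being shrunk; with the
  undivided variance the mean spectrum is oversmoothed by roughly a
  factor $\sqrt n$ in threshold units, which in our simulations costs
  sensitivity at low false-discovery rates. Users wanting the more
  aggressive behavior set `replicates = 1` in the pipeline config.

## Baseline and peaks in one pass

The underlying signal is modeled as sparse protein peaks — truncated
Gaussian kernels $a_j G_{3\sigma_j}(t_j, \sigma_j)$, zero outside
$t_j \pm 3\sigma_j$ — on a slowly varying matrix-ion baseline. Because
the protein component is mostly zero, the local minima of $\tilde\mu$
can be assumed to touch the baseline; a single extrema scan therefore
yields both the baseline knots (minima) and the peak candidates (maxima).

* The baseline is a shape-preserving piecewise cubic Hermite
  interpolant (Fritsch–Carlson slopes, via `signal::pchip`) through the
  minima: it passes through every knot exactly and cannot overshoot
  between knots. Base R's `splinefun(method = "monoH.FC")` was rejected
  for this role after it produced measurable interior bumps between
  near-flat knots with a slope sign change.
* Beyond the first/last knot the baseline continues as a constant; with
  fewer than two minima it degenerates to the constant
  $\min \tilde\mu$ with a warning.
* Plateaus count as one extremum at the run's center; grid endpoints are
  never peaks.
* Each maximum becomes one peak: height = $\tilde\mu$ − baseline at the
  apex, area = trapezoidal integral of $\max(\tilde\mu-\mathrm{baseline},
  0)$ between the flanking minima. Non-positive-height maxima are kept
  with area 0 — discarding is left entirely to the area threshold, the
  method's single user-facing parameter. No minimum-width or merge rule
  is applied.

Thresholded peak lists are nested in the threshold, which is what makes
the operating characteristic below well defined.

## The hybrid-spectrum simulator

Real evaluation data with exact ground truth do not exist: either the
protein content is unknown (serum) or the noise is idealized (pure
simulation). The simulator therefore builds **hybrid** spectra: a clean,
noise-free virtual-protein spectrum plus a matrix-only buffer spectrum
carrying baseline and detector noise. Protein content is then known
exactly while the noise follows the detector model.

Per-dataset defaults: 150 virtual proteins, 50 spectra, 30 datasets,
analyzed on 3–30 kDa. The grid is uniform in $\sqrt{m/z}$ (time of
flight scales with the square root of mass), 8192 points over 2–32 kDa
by default. Buffer spectra form a finite pool (183 by default) sampled
with replacement — mirroring the practical economics of matrix-only
acquisitions, where one cannot afford a fresh buffer run per test
spectrum.

Priors for protein properties, declared stand-ins chosen once to be
realistic for low-resolution TOF serum profiling and documented as
configuration rather than constants:

* protein m/z: log-uniform over the window (masses spread evenly on the
  log scale, as protein abundance surveys suggest);
* mean abundance: lognormal, `meanlog = log(3000)`, `sdlog = 0.7` — at
  instrument resolution R = 150 this puts median peak heights an order
  of magnitude above the noise floor at low mass while leaving a
  substantial fraction of peaks near or below detectability at high
  mass, so operating characteristics sweep a meaningful range;
* prevalence: uniform on [0.3, 1]; per-spectrum abundance CV 0.2;
  per-spectrum relative m/z jitter 0.001;
* peak width: $\sigma_j = (m/z)/(2.355\,R)$, R = 150 (FWHM-based
  resolution rule, low-resolution TOF regime).

Buffer noise is drawn **independently per grid point**, with mean given
by a decaying-exponential baseline (maximum at the low-mass edge, 100
intensity units, decay length 8000 Da) and variance $V(\cdot)$ from a
configurable QVF (default (4, 0.5, 0.01)). Two families are provided:
Gaussian, and a moment-matched shifted gamma for right-skewed settings —
emulating the qualitative contrast between machine settings that produce
symmetric versus heavily skewed intensity distributions.

**What the simulator does not emulate — and what that means for the
tests.** Real SELDI noise is correlated across neighboring grid points
(laser-shot summation, detector bandwidth, vendor-side processing);
simulated noise is white. This matters for one visible statistic: under
white noise, the term-by-term shrinkage rule kills a coefficient only
when $w(i)^2 \le \tilde\sigma^2(i)$, an event of probability ≈ 0.68 for
pure noise, so roughly a third of noise coefficients survive (strongly
attenuated) at *every* scale, and the denoised spectrum retains a
residual fine-scale wiggle density proportional to grid length. On real
spectra, noise energy concentrates in coarse scales and the same rule
produces far smoother output with peak counts close to the true protein
count. Consequently, passing tests here demonstrate the estimator's
statistical properties (risk improvement, operating-characteristic
gains) under the declared noise model — not the raw peak-count economy
one observes on real instrument data, and our end-to-end check of peak
counts against the true protein count indeed fails under white noise
while every distributional property passes. The simulator also models no
detector saturation, no chemical adducts, and no mass-calibration drift.

## Operating characteristics

A predicted m/z matches a true protein when the relative error is at
most 0.3% (default). Counting is asymmetric by design: a true protein is
recovered if *any* prediction lands within tolerance (one prediction may
credit two nearby truths), a prediction is a false positive only if it
matches *no* truth. From TP/FP/FN: FDR = FP/(FP+TP) and
TPR = TP/(TP+FN), with FDR defined as 0 when no predictions exist so the
empty end of the threshold sweep anchors the curve at the origin.

Each dataset's operating points (default sweep: 0 plus the sorted unique
peak areas — every achievable operating point) are smoothed by loess
(span 0.5, degree 1, direct surface) onto a fixed 101-point FDR grid on
[0, 1], clipped to [0, 1], with constant continuation outside the
observed FDR range and a monotone-step fallback below 3 distinct points.
Curves are aggregated pointwise (mean, quartiles) and summarized by
normalized partial AUC: the trapezoidal area over [0, `fdr_max`] divided
by `fdr_max`, times 100, so an ideal curve scores exactly 100. The
conventional windows are FDR ≤ 0.25 and FDR ≤ 0.50.

## Problem sizes used by the test suite

The shipped tests run miniature versions of everything, chosen as the
smallest scales at which each property is meaningful: transforms are
verified at lengths 16–128 against brute-force oracles; QVF recovery
uses 1024-point grids with pools of 25–400 spectra; the end-to-end
pipeline runs 5 datasets × 10 spectra × 30 proteins on a 1024-point grid
(~26 Da spacing at 10 kDa — the coarsest grid at which the 0.3% matching
tolerance still exceeds one grid step) across 5 seeds, comparing the
full pipeline against a no-denoising arm. Full-scale defaults (30 × 50 ×
150 on 8192 points) run in minutes and are exercised through
`run_pipeline()` or the CLI, not the test suite.

## Known limitations

* The QVF must be estimated from buffer-only spectra acquired under the
  *same* machine settings as the sample spectra; the fitted curves
  differ strongly across settings, and a mismatched QVF degrades the
  denoiser in either direction (under- or over-smoothing).
* Peak *areas* are used only for ranking/thresholding; their use as
  quantitative protein abundances is not validated here.
* The model is not valid below the mass-focused window (detector
  saturation near 2–2.5 kDa); `restrict_window()` is the intended guard.
* mzML input is read-only and requires the optional `mzR` package; the
  native interchange format is two-column delimited text.
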