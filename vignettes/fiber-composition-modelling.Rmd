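---
title: "Modelling palm-fiber mechanics from lignocellulose composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling palm-fiber mechanics from lignocellulose composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberGM)
```

Windmill palm fiber (WPF) is a coarse lignocellulosic fiber whose
suitability for spinning depends on its mechanical properties, which in
turn track its chemical composition: cellulose and lignin stiffen the
fiber, hemicellulose softens it. fiberGM implements the computational
chain that links these quantities: extracting Young's modulus from
single-fiber tensile tests by the system-compliance method, a
multivariate grey model relating composition to modulus, and the NIR
chemometrics protocol used to predict composition without wet chemistry.
This vignette explains each model, the choices behind the implementation,
and what the synthetic-data generators do and do not emulate.

## The system-compliance method

A single-fiber tensile test measures total crosshead displacement
$\Delta L$ at breaking force $F$. The measured compliance
$\Delta L / F$ contains both the fiber's own compliance and that of the
load train (grips, frame). For a linearly elastic fiber of gauge length
$L_0$, cross-sectional area $A$ and Young's modulus $E$,

$$\frac{\Delta L}{F} = \frac{1}{E}\,\frac{L_0}{A} + C_s,$$

so regressing $\Delta L/F$ (mm/N) on $L_0/A$ (1/mm) across tests at
several gauge lengths gives $E$ as the reciprocal of the slope
(mm$^2$/N $\equiv$ 1/MPa) and the system compliance $C_s$ as the
intercept. `fit_compliance_line()` uses ordinary least squares with an
intercept; the published per-sample fits show only the fitted line, and a
straight-line fit is the standard reading of the method. Negative
intercepts are accepted — they occur in the published fits and merely
indicate a small load-train correction estimated below zero — but a
non-positive slope has no physical interpretation (it would imply
non-positive stiffness) and raises an error carrying the fitted value.
Raw test records are reduced to regression points by exact division;
replicates at a gauge length are kept as individual points unless
averaging is requested, since the source protocol does not state
replicate aggregation.

## The grey model GM(1,N)

The grey model treats the modulus sequence of $n$ samples as a reference
series $X_0$ driven by $m$ comparative series $X_1..X_m$ (here $m = 3$:
cellulose, hemicellulose, lignin, giving GM(1,4)). The algebra:

1. **Initialization** (`grey_initialize`): every series is divided by its
   first element, removing units and scale.
2. **Accumulated generating operation** (`grey_ago`): the running
   cumulative sum of the initialized series, smoothing sample-to-sample
   randomness.
3. **Mean-generating sequence** (`grey_mean_sequence`):
   $Z_1(k) = \tfrac12\left(X_0^{(1)}(k-1) + X_0^{(1)}(k)\right)$ for
   $k = 2..n$.
4. **Estimation** (`grey_estimate`): the grey differential equation
   $$X_0^{(0)}(k) = \sum_{i=1}^{m} b_i X_i^{(1)}(k) - a\,Z_1(k)$$
   is solved for $(a, b_1..b_m)$ by least squares over $k = 2..n$.

A positive grey action quantity $b_i$ marks series $i$ as a promoter of
the reference, a negative one as an inhibitor; $a$ is the development
coefficient. `grey_fit_report()` evaluates per-$k$ predictions, relative
errors $|\hat y - y|/y$ and their arithmetic mean.

Numerical choices:

* The source material writes the mean-generating index as $k+1$, but its
  own sequence table uses consecutive-pair means at $(k-1, k)$; the table
  convention is implemented because it is the one the published numbers
  satisfy.
* The design's mean-term column carries a negative sign so the solved
  vector matches the equation as written, with a positive development
  coefficient.
* Estimation uses a QR solve rather than the textbook
  $(B^TB)^{-1}B^TY$ inverse; equivalence to the normal-equations formula
  on well-conditioned designs is a test, not the implementation.
* Rounding for comparisons against published values rounds half away
  from zero to 2 decimals, with an extra $\pm 0.01$ where inputs are
  themselves 2-dp-rounded.

### Reproduction modes

The published tables are internally inconsistent in places (see
`consistency_report()`): five compliance rows print a modulus that is not
the reciprocal of their printed slope; one cumulative value disagrees
with the moduli that generate the column; and no printed cumulative
column matches any composition sequence at every $k$, leaving the mapping
of the first comparative column onto a specific component ambiguous.
`grey_reproduction()` therefore runs in two modes: `"printed"` feeds the
published cumulative/mean sequences and published coefficients through
the prediction step (reproducing the published error analysis), while
`"recomputed"` rebuilds everything from the composition and compliance
tables and re-estimates the coefficients. In recomputed mode both
comparative orderings are available (`"stated"`: cellulose,
hemicellulose, lignin; `"table_evidence"`: the ordering the printed
columns' partial matches suggest), because the source is genuinely
ambiguous and the package does not guess. Coefficients re-estimated from
the printed design are attached as a diagnostic with their deviation from
the published values; exact agreement cannot be asserted since the
printed design inputs are rounded to 2 decimals.

## The NIR calibration protocol

Composition is predicted from near-infrared absorbance spectra
(4,000–12,000 cm$^{-1}$) by per-component partial least squares after a
preprocessing chain of vector normalization, Savitzky–Golay first
derivative and standard normal variate (SNV), in that order — the order
in which the source lists them; the chain is configurable because the
composition of the three steps is not specified there. Savitzky–Golay
defaults are window 15, polynomial order 2, common NIR practice.

PLS is single-response NIPALS with mean centering and no predictor
scaling, which for one response reduces to the deterministic closed-form
weight $w = X^T y / \|X^T y\|$ per latent variable. Calibration quality
is summarized by RMSEC and $R_c^2$ on the training fit and RMSEP and
$R_{cv}^2$ from leave-one-out cross-validation (the
smallest-assumption reading of a paired RMSEP/$R_{cv}^2$ report;
per-spectrum preprocessing is re-applied inside each fold). Factor
selection minimizes cross-validated RMSEP with ties broken toward fewer
factors. $R_{cv}^2$ is reported unclamped and can be negative for
uninformative predictors.

External validation compares measured and predicted contents on held-out
samples with a paired two-tailed $t$-test:
$t = \bar d / (s_d/\sqrt{n})$ with $d$ = predicted − measured and the
$n-1$ sample standard deviation, judged against the two-sided critical
value at $\alpha = 0.05$ with $n-1$ degrees of freedom (4.303 for three
validation samples). The published wavelength note mixes a nm interval
with a cm$^{-1}$ range, so the true instrument grid spacing is
unknowable; the synthetic grid defaults to 4 cm$^{-1}$ steps over the
stated cm$^{-1}$ range.

## What the synthetic data emulate

No spectra or raw tensile curves are deposited with the source material,
so the package ships seedable generators that produce inputs with the
statistical structure the analysis assumes. All generators are pure
functions of (configuration, seed); one seed expands into fixed
per-generator substreams.

**Composition profiles** (`simulate_components`). The measured sample
set is a degumming series: progressive chemical removal of lignin (and
gums) enriches cellulose, making the two almost perfectly anti-correlated
(correlation $-0.99$ in the measured table), while hemicellulose varies
in a narrow band across samples. The default generator reproduces this
structure with a latent degumming degree $d \sim U(0,1)$ driving
cellulose up (8.0 → 80.5 %) and lignin down (76.5 → 4.2 %), independent
hemicellulose within its observed range, and 0.3 % Gaussian measurement
noise per content, rejection-sampled so every content stays within the
observed extremes and the three sum to at most 100 %. This structure
matters: the preprocessing chain removes each spectrum's absolute scale,
so composition must be recoverable from band *ratios*; along a degumming
trajectory it is, whereas for three mutually independent contents the
narrow-range component would be unidentifiable in principle from
scale-corrected spectra — a property of the chemistry being emulated,
not of the calibration. An `"independent"` structure (uniform draws,
sum ≤ 100 only) remains available for stress tests.

**Spectra** (`simulate_spectra`). Beer–Lambert mixtures: each component
contributes a fixed set of 5–6 Gaussian bands in the 4,000–9,000
cm$^{-1}$ overtone/combination region, deliberately overlapping between
components so the calibration is neither trivial nor degenerate; band
positions are generic lignocellulose-like choices for simulation, not
assignments of measured bands. Each sample is degraded by a
multiplicative scatter factor (0.7–1.3, the particle-size-driven scatter
magnitude that makes SNV necessary in powder diffuse reflectance), a
linear baseline (offset 0–0.3 AU, slope $\pm 2\times10^{-5}$
AU/cm$^{-1}$) and additive noise (0.002 AU). The generator does **not**
emulate nonlinear detector response, wavelength-dependent scatter
curvature, water-vapour interference, or real band assignments — so
passing synthetic tests demonstrates that the protocol is implemented
correctly and behaves as designed under its own assumptions, not that
the published calibration statistics are reproducible; those depend on
undeposited spectra and are deliberately not reproduction targets. When
both the full chain and raw spectra already calibrate near the noise
ceiling, their cross-validated ranking can invert within a few
thousandths; the preprocessing comparison is therefore meaningful only
at the replicate level.

**Tensile points** (`simulate_tensile`). The published design: gauge
lengths 20/30/40 mm, 15 replicates each (45 tests per sample), lognormal
fiber areas with median ≈ 0.08 mm$^2$ (coarse palm fibers), Gaussian
noise on $\Delta L/F$ (default 0.02 mm/N).

**Grey systems** (`simulate_grey_system`). The defining equation solved
forward for the reference increment,
$X_0^{(0)}(k) = \left[\sum_i b_i X_i^{(1)}(k) - a X_0^{(1)}(k-1)\right] /
(1 + a/2)$, which requires $1 + a/2 \neq 0$; noise-free output satisfies
the grey equation to machine precision and round-trips through
estimation to $10^{-8}$.

## Problem sizes and tolerances in the tests

The test suite runs the reproduction checks on the full packaged tables
(they are desk-scale: 26 composition rows, 15 tensile fits) and the
synthetic properties at sizes chosen to exercise the algebra without
waste: spectra on 251–501-point grids for property tests and the full
2,001-point default grid for the end-to-end calibration check; 26-sample
calibrations with 3 held-out samples, matching the source design; grey
systems of length 12–15. Oracle equivalences (OLS, normal equations,
LOO refits, t-test) are asserted at $10^{-8}$–$10^{-12}$; reproduction
of printed values is asserted at printed precision ($\pm 0.01$ on
2-dp tables, exact at 3 dp for the t statistics).

## Known limitations

* The grey model is the algebraic GM(1,N) fit; whitenization
  differential-equation solutions, GM(1,1) forecasting and grey
  relational analysis are out of scope.
* The published PLS calibration statistics (their Table of RMSEC/RMSEP
  per component) are not reproducible without the spectra and are not
  targets; only the external-validation endpoints, which are fully
  printed, are reproduced.
* The comparative-column ambiguity in the published sequence table means
  recomputed-mode coefficients depend on the chosen ordering; the
  package reports both rather than resolving the ambiguity.
* Fixture values are stored verbatim, including their internal
  inconsistencies; corrections appear only in the errata report and in
  explicit recomputation, never silently.
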