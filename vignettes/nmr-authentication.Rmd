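---
title: "Chemometric authentication of honeysuckle flos from 1H-NMR fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric authentication of honeysuckle flos from 1H-NMR fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrpattern)
```

## The problem

Lonicerae japonicae flos (LJF, the flower bud of *Lonicera japonica*) is a
widely used medicinal and food plant; Lonicerae flos (LF, *Lonicera
macrantha*) is its common substitute.  The two are morphologically similar but
chemically distinct — LF is rich in triterpenoid saponins (macranthoidin A,
macranthoidin B, dipsacoside B) that are present only in traces in cultivated
LJF — and pharmacopoeias treat them as separate items.  A ¹H-NMR spectrum of
an aqueous extract records every proton-bearing constituent at once, so a
whole-spectrum fingerprint plus pattern recognition can authenticate material
without compound-by-compound assays.  `nmrpattern` implements that workflow
end to end: spectral bucketing, unsupervised overview (PCA), supervised
latent-variable models (PLS-DA, OPLS-DA) with VIP-based variable selection
and permutation validation, and stepwise Fisher linear discriminant analysis.

## From spectrum to feature matrix

A spectrum enters as a (chemical shift, intensity) trace.  The region
δ −0.025 to 9.975 ppm is integrated in 0.05-ppm sections (trapezoidal rule on
the piecewise-linear trace; half-open windows so no grid point is counted
twice), giving 200 bucket variables per sample.  Buckets are numbered V1 …
V200 **descending** in ppm: V1 covers 9.925–9.975 ppm and V200 covers the
tetramethylsilane (TMS) reference around 0.0 ppm.  This convention follows
the published stepwise-LDA variables: under it, V186 spans 0.675–0.725 ppm
and V184 spans 0.775–0.825 ppm (both inside the saponin methyl region
0.65–1.80 ppm) while V147/V145 span 2.625–2.675/2.725–2.775 ppm (the
secoiridoid region); the ascending convention would scatter those variables
into chemically meaningless regions.

Every row is normalized by the integral of the TMS bucket, which then equals
exactly 1.0.  This removes the per-sample intensity scale (receiver gain,
extract mass): multiplying a whole trace by a constant leaves the normalized
row unchanged.  We interpret "the TMS peak" as the bucket *integral* rather
than the point maximum — the two differ only by a constant factor on an
idealized Lorentzian, and the integral is robust to grid density; the choice
is switchable by normalizing manually.

Column scaling for latent-variable models defaults to unit variance (UV,
mean-centering plus division by the column standard deviation), the
convention of mainstream chemometrics software for bucketed NMR data.
Centering-only and Pareto scaling are available; see the S-line note below
for why Pareto matters there.  No solvent regions are excluded by default —
the workflow this mirrors modelled all 200 buckets — but any window can be
dropped by subsetting the bucket table.

## Latent-variable models

**PCA** uses NIPALS with deterministic initialization (the column of largest
variance) and a sign convention (largest-magnitude loading entry positive),
so fits are exactly reproducible.  Cross-validated Q² uses Wold elementwise
deletion: matrix elements are removed in 7 diagonal stripes, each component
refit with the deletions treated as missing, and PRESS accumulated over
deleted elements; cumulative Q² is `1 − prod(PRESS_a/SS_a)`.  With
`stop_rule = "q2"`, extraction stops when a component's Q² falls below 0
(the usual significance rule).  The exact deletion scheme of commercial
software is proprietary, so numerical equivalence with published R²X/Q²
values is approximated, not guaranteed.

**PLS-DA** codes classes as one-hot indicators, scales the indicator columns
to unit variance (so small classes are not swamped), and runs NIPALS PLS2
with deflation of both blocks.  R²Y accumulates the explained indicator
variance; Q² comes from stratified 7-fold cross-validation, re-fitting on
each training fold and accumulating PRESS over held-out rows against the
pooled scaled-Y sum of squares.  The component count is chosen by a
cross-validation rule: add components while cumulative Q² improves by more
than 0.01.

**OPLS-DA** first removes structured X-variation orthogonal to the class
space (for one response the classical weight `w_o = p − (w'p)w`; for
multi-class Y the loading is projected out of the span of all Y-column
weights), then fits the predictive components on the filtered matrix.  With
zero orthogonal components it reduces exactly to PLS-DA.  Predictive scores
are orthogonal to every orthogonal score by construction, and the explained
X-variance splits into predictive and orthogonal parts.

**VIP** (variable importance in projection) is
`VIP_j = sqrt(p * sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a)`; its mean
square is 1 by construction, so VIP > 1 marks above-average contributors.
The screening criterion is strictly greater than the threshold.

**The S-line** reports, per variable, the covariance and correlation between
the variable and the first predictive OPLS score.  One numerical subtlety
matters: on UV-scaled data every column has variance 1, so p(cov) collapses
onto p(corr) and weak tail buckets rank equally with intense peak centers.
The S-plot/S-line convention therefore pairs this diagnostic with
centered-only or Pareto scaling, which retains the intensity dimension; the
package computes the S-line on whatever matrix is supplied, and the bundled
analyses use Pareto scaling for it.

**Permutation validation** refits the model at fixed component count under
randomly shuffled class rows (200 rounds by convention), recording the
correlation between permuted and original indicators alongside R²Y and Q².
Intercepts of the least-squares lines of R²Y and Q² against the correlation
— including the unpermuted reference point, as in the standard validate plot
— diagnose over-fitting: a sound model shows a clearly negative Q² intercept
and a real Q² above the permuted distribution.

## The variable-selection cascade

The two-stage reduction mirrors the published flow diagram: (1) PLS-DA on
the full 200-bucket training matrix, keep VIP > 1; (2) refit PLS-DA *and*
OPLS-DA on the reduced matrix, screen each by VIP > 1 again, and intersect.
Variable identity is tracked by original V-index throughout, so reduction
never shifts indices.  Because VIP has unit mean square, the second stage
necessarily drops roughly half of a reduced matrix in which most surviving
variables are informative — the same mechanism that took the study's 75
variables to 42/43 and a 35-variable intersection.  Recovery of planted
markers is therefore a property of the *screening* stage; the intersection
trims towards the strongest contributors.  Stage-wise component counts are
chosen by the Q²-improvement rule rather than fixed, since the source
workflow does not state them.  The stage-2 OPLS-DA uses the multi-class
(full dummy-Y) orthogonalization; a pairwise-union reading of the flow is
possible but was not taken, because the study fitted three-class models
throughout.

## Stepwise linear discriminant analysis

Stepwise selection greedily minimizes Wilks' Λ with probability-of-F
thresholds `p_enter = 0.05`, `p_remove = 0.10` (the defaults of the
statistics software named by the source workflow).  Candidates producing a
singular within-class scatter are skipped with a warning.  The fitted model
exposes per-class Fisher classification functions
`f_g(x) = μ_g'Σ⁻¹x − ½μ_g'Σ⁻¹μ_g + log π_g` over the pooled within-class
covariance Σ; argmax over classes equals the Gaussian Bayes rule with shared
covariance, which the test suite checks against a brute-force Mahalanobis
oracle.  Priors default to equal across classes (the software's default; the
source is silent), configurable to proportional.  Variables are *not*
standardized inside LDA — classification functions are in raw
TMS-normalized bucket units, matching the scale of the published
coefficients, which `published_lonicera_functions()` bundles for direct
evaluation.  A singular pooled covariance receives a one-time diagonal ridge
of `1e-8 × trace/p`, logged.  Leave-one-out cross-validation refits without
each sample; if leaving one out orphans a singleton class, that refit is
scored unclassifiable rather than aborting the whole loop.  Statistics
software sometimes computes stepwise statistics on the pooled
correlation rather than covariance matrix; selection order can differ in
borderline cases, which is flagged here rather than guessed.

## The synthetic cohort generator

No spectra are deposited with the source study, so the generator stands in
for its 100-batch cohort (77 cultivated LJF, 10 wild LJF, 13 LF).  Each
spectrum is a constant baseline plus, per marker compound, a log-normally
drawn abundance scaling all of that compound's Lorentzian resonances
jointly, plus a TMS reference Lorentzian at 0.0 ppm and additive Gaussian
noise, on 16,384 grid points over −0.525 to 10.475 ppm (headroom so edge
buckets never touch the grid ends).  The Lorentzian (Cauchy) line shape is
the natural-linewidth model of an NMR resonance; the log-normal abundance
law keeps concentrations positive and right-skewed, as natural abundances
are.

The compound library places resonances in the windows the study attributes
to its markers: the three saponins in 0.65–1.80 ppm; secoxyloganin and
secologanoside in 2.65–2.95, 4.60–4.70 and 5.20–5.30 ppm; sweroside in
5.50–5.55 ppm.  Exact centers, half-widths (0.01 ppm) and relative heights
within those windows are free parameters documented as constants — the study
reports windows, not assignments.  Default class profiles encode the
reported biology: saponins high in LF, intermediate in wild LJF, trace in
cultivated LJF; secoiridoids and sweroside elevated in wild LJF.  The
abundance coefficient of variation (0.25), baseline (0.01), noise (0.01) and
TMS height (5) were chosen once as a plausibly realistic regime for
TMS-referenced extract spectra.  The binary `processing_design()` contrasts
hot-air and sun drying as the same cultivated-LJF profile with a modest
(default +20%) secoiridoid elevation in the sun-dried class — a deliberately
weak contrast, since processing perturbs composition far less than species
identity; with it the binary OPLS-DA lands in the good-fit/-poor-predictivity
regime the study reports for this contrast.

Every random draw derives from a single integer seed through hashed,
per-stage child seeds (`derive_seed()`), so any sample or stage can be
regenerated in isolation and toggling one stage never shifts another's
stream.

What the generator does *not* emulate: J-coupling multiplet structure,
chemical-shift jitter between samples, residual-solvent and water bands,
baseline roll, and peak-shape distortions from imperfect shimming or
phasing.  Passing tests on synthetic cohorts therefore demonstrate that the
statistical machinery behaves correctly on data with the assumed structure —
they do not certify performance on real spectra, where alignment and solvent
exclusion (both out of scope here) often matter as much as the modelling.

## Numerical choices

* NIPALS convergence: relative score change < 1e-10, at most 500 iterations;
  deterministic starts (largest-variance column) and a sign convention
  remove run-to-run ambiguity.
* Cross-validation: 7 stratified folds by default; a fold that would swallow
  an entire class is repaired with a warning.  Ties in class prediction go
  to the lowest class index.
* Zero-variance columns (the TMS anchor is constant by construction) pass
  through centered with a warning and get correlation 0 in the S-line.
* Bucket windows are half-open `[low, high)` with the last closed; bucket
  integrals are exactly additive and sum to the full-range integral.

## Problem sizes

The test suite exercises cohorts of 28–32 samples for unit-level checks and
the full 100-sample default design for the acceptance-style properties
(20-seed marker-recovery and S-line localization loops, 50-round permutation
checks, 10-seed null-design checks).  The bundled acceptance script runs the
complete species and processing analyses, each with 200 permutation rounds,
on the 100-sample and 77-sample default designs respectively.  These sizes
were chosen to match the study's cohort dimensions while keeping a full run
in the order of seconds to a few minutes on one CPU.

## Known limitations

* Equivalence with commercial implementations (PCA cross-validation
  grouping, multi-class OPLS deflation) is by documented convention, not
  bit-compatibility; published R²/Q² values from the real cohort are not
  reproduction targets because those spectra are unavailable.
* The stepwise LDA explores entry/removal greedily; it does not guarantee
  the globally optimal subset, matching the behaviour of the software it
  mirrors.
* The pipeline assumes TMS-referenced, baseline-corrected input; no peak
  alignment or phasing is performed.
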