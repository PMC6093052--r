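---
title: "Calibrating flavonoid content and antioxidant activity from NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating flavonoid content and antioxidant activity from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirflav)
```

## The problem

Total flavonoid content (TFC) is a principal quality index of *Ginkgo
biloba* leaf and similar botanical material, and it is tightly coupled to
total antioxidant activity (TAA) as measured by DPPH radical scavenging.
Both reference assays are wet-chemical: TFC is read off a rutin calibration
line after a colorimetric reaction, TAA off a Trolox calibration of
scavenging fractions. They are accurate but slow and destructive.
Near-infrared diffuse-reflectance spectroscopy offers a fast,
non-destructive surrogate: overtone and combination bands of C–H, O–H and
N–H bonds between 4000 and 8000 cm⁻¹ carry compositional information that a
multivariate calibration can map onto the assay values.

This package implements that calibration workflow as a tested pipeline:
spectral preprocessing, outlier screening, representative sample
partitioning, latent-variable regression with cross-validated complexity
selection, and honest held-out evaluation.

## The model

The core regression is single-response partial least squares (PLS1) fitted
by NIPALS. Predictors `X` (n samples × p wavelengths of log(1/R)
pseudo-absorbance) and response `y` are mean-centered; no variance scaling
is applied, the usual choice in NIR work where the spectral variance
structure is informative. Each latent factor extracts a weight vector
`w ∝ X'y`, scores `t = Xw`, loadings `p = X't/t't`, `q = y't/t't`, and
deflates `X` before the next factor. The factorization collapses to a
single regression vector `B = W(P'W)⁻¹q`, so prediction is
`ŷ = (X − x̄)B + ȳ`. With one response the inner NIPALS iteration is
stationary after one pass; the iterative form (tolerance 1e-12, cap 500) is
kept for robustness.

Model complexity — the factor count `A` — is selected at the minimum of the
10-fold cross-validated error (ties to the smaller `A`):

* folds are contiguous blocks of a seeded random permutation, sizes
  differing by at most one;
* `RMSECV(A) = sqrt((1/n) Σ (ŷᵢ − yᵢ)²)` with every `ŷᵢ` produced by the
  model fitted without sample *i*'s fold;
* the error metrics RMSEC (calibration) and RMSEP (prediction) share the
  same root-mean-square form over their respective sets.

For correlation reporting the package computes `r² = 1 − SSE/SST` and
`r = sqrt(max(r², 0))` and returns **both**. Reporting conventions in the
NIR literature are ambiguous between quoting `1 − SSE/SST` itself and its
square root; returning both avoids silently choosing.

## Workflow order and leakage control

`run_calibration_workflow()` executes, in order: id alignment → one-shot
outlier removal → Kennard–Stone split → preprocessing-candidate comparison
by minimum RMSECV on the calibration set → factor selection → final fit →
evaluation on the untouched prediction set.

Two ordering decisions deserve emphasis:

* **Outlier removal happens once, before splitting.** No iterative
  re-screening after removal; the screen's verdict is final for a run. This
  mirrors the usual practice of cleaning the sample set before building
  calibration and validation subsets.
* **Nothing downstream of the split sees prediction-set rows.** The MSC
  reference spectrum is the calibration-set mean (frozen by `fit_chain()`
  and reused for the prediction set), cross-validation and centering use
  calibration rows only. The Kennard–Stone selection itself necessarily
  measures distances among all retained samples — that is what the
  algorithm is — so the workflow also accepts a precomputed `split`,
  which is how the test suite audits that perturbing prediction rows leaves
  the fitted model bit-identical.

## Preprocessing families

Four families are implemented, composable in ordered chains:

* **SNV** — per-spectrum standardization to mean 0, sd 1 (n−1
  denominator throughout the package), removing per-sample additive offsets
  and multiplicative scatter exactly.
* **MSC** — least-squares regression of each spectrum on a reference
  (default: mean spectrum), corrected to `(x − a)/b`.
* **Moving-window smoothing** — centered running mean; edge windows are
  truncated so `p` is preserved.
* **Savitzky–Golay** — local polynomial least squares via `signal`'s
  filter matrices, which fit boundary polynomials so no points are lost.
  Derivatives are reported per cm⁻¹ (division by `spacing^deriv`, signed,
  so descending instrument grids keep the correct sign). The default window
  11 / polynomial order 2 is a conventional choice, exposed in the
  configuration.

Candidate chains are compared by their minimum RMSECV; ties go to the
shorter chain. The default candidate set is raw, SNV, MSC, moving window
(11), and SG first and second derivatives (11, 2).

## Outlier screening

Screening happens in a PCA score subspace (smallest k explaining ≥ 99 % of
variance, capped at 10 — the subspace used for distance screening is
otherwise arbitrary and this rule is stated and overridable). Two measures
are combined by union:

* **Mahalanobis distance** `dᵢ = sqrt((xᵢ−x̄)' S⁻¹ (xᵢ−x̄))` on score rows,
  flagged when `dᵢ²` exceeds the χ²(k) quantile 0.975;
* **leverage**, the hat-matrix diagonal of `[1 | scores]`, flagged above
  `3·m/n`.

Both cutoffs are standard chemometric conventions rather than theory-driven
constants, and both are configurable. Leverages of a full-rank design sum
to its column count and lie in [0, 1]; these invariants are tested.

## The synthetic data generator

Because measured spectra for the 113-batch reference table are not
available, the package ships a generator whose defaults emulate the study
conditions: n = 113 samples on a 4150-point grid over 4000–8000 cm⁻¹,
with

`xᵢ(ν) = bᵢ·(Σₖ cᵢₖ sₖ(ν) + baselineᵢ(ν)) + aᵢ + εᵢ(ν)`.

* **Constituents** are Gaussian band mixtures: a flavonoid fraction (main
  band at 5352 cm⁻¹, the carbonyl second-overtone region), moisture (the
  intense O–H bands at 6900 and 5180 cm⁻¹, dominating total absorbance as
  in real plant-powder spectra), and a non-flavonoid phenolic fraction.
  Flavonoid concentrations span 1.47–49.20 mg/g, the range of the packaged
  reference table. Matrix dominance matters: the analyte contributes a
  minor share of total spectral variance, which keeps per-spectrum
  normalizations (SNV's row sd, MSC's slope) nearly composition-independent
  — the regime in which these corrections are linear and effective, and the
  regime real leaf-powder spectra occupy.
* **TAA link.** The packaged table shows TAA ≈ 0.0782·TFC + 0.591 with
  residual sd 0.416 (r² ≈ 0.81). Its per-sample sd column puts assay
  repeatability at ≈ 0.141 mM/g, so only that much is modelled as
  irreducible noise; the remaining scatter (sd ≈ 0.391) is attributed to
  the spectrally active phenolic co-constituent. This keeps both observed
  properties at once: the table-level TFC–TAA coupling, and the spectral
  recoverability of TAA beyond what TFC alone explains (a pure
  TFC-plus-noise link at the observed residual sd would cap achievable TAA
  r² near 0.81). TAA is truncated at 0.
* **Nuisance terms**: a quadratic per-sample baseline (offset 0.3,
  coefficient sd 0.02 AU), multiplicative scatter `bᵢ ~ 1 + N(0, 0.05)`,
  additive offsets `aᵢ ~ N(0, 0.02)`, and white noise sd 5·10⁻⁴ AU
  (FT-NIR-like repeatability after scan averaging). The instrument's true
  noise figures are not published; these are stated conventions.
* `scatter_corrupted_config()` defines the scatter-stress scenario: pure
  per-sample affine corruption (slope sd 0.25, offset sd 0.15, no random
  baseline) — exactly the corruption SNV is designed to remove, used for
  the preprocessing comparison.

What the generator does **not** emulate: Kubelka–Munk/radiative-transfer
scattering physics, wavelength-dependent scatter, instrument drift, band
shifts with temperature or moisture state, and non-Gaussian band shapes.
Passing the recovery tests therefore shows the pipeline's statistical
machinery is correct under its own assumptions, not that any particular
accuracy will be achieved on real spectra.

## Numerical choices

* Standard deviations use the n−1 denominator everywhere.
* Kennard–Stone ties (duplicate points) break to the lowest index, making
  the split fully deterministic.
* `A_max` defaults to `min(20, n_cal − ceil(n_cal/folds) − 1, p)`; an
  infeasible request is reduced with a warning. If the response is fitted
  exactly before `A_max` factors, the RMSECV curve continues flat rather
  than failing, and the tie rule then selects the smaller count.
* Degenerate inputs fail loudly: constant spectra (SNV), near-zero MSC
  slopes, singular score covariances, rank-deficient designs and
  zero-variance responses all raise named errors instead of propagating
  NaNs.
* Model archives are JSON at 17 significant digits, which round-trips
  doubles bit-exactly.
* One pipeline seed fans out to fixed per-stage seeds, so a config + seed
  pair reproduces every number byte-identically.

## Problem sizes used in the tests

Unit and property tests run on reduced problems (tens of samples, 50–300
grid points) chosen to exercise every code path; the end-to-end recovery
checks and the acceptance script run at the full study scale (113 × 4150,
10-fold CV, six candidate chains). At that scale a complete two-target run
takes well under a minute on a single core.

## Known limitations

* PLS1 only — TFC and TAA are calibrated separately (as in the reference
  workflow); no PLS2, SIMPLS or kernel variants.
* No wavelength-interval or variable selection (iPLS, CARS and relatives
  are out of scope).
* Outlier screening uses classical (non-robust) covariance; a mass of
  coordinated outliers could mask itself.
* The reference table's printed anomalies are preserved, not repaired: the
  duplicate label "16" is kept (records are keyed by position), and no
  attempt is made to reconcile stated sample counts elsewhere in the
  source; all counts are derived from the data.
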