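---
title: "Monitoring grazing intensity from fused visible and multispectral imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring grazing intensity from fused visible and multispectral imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazspec)
```

## The problem

Grazing pressure on semi-arid sandy grasslands leaves a spectral fingerprint.
As stocking rates rise, vegetation cover drops and bright sandy soil shows
through, so visible-band brightness increases — until trampling crusts the
surface under severe grazing and brightness dips again. In the multispectral
domain, green and red reflectance rise monotonically with grazing, while
red-edge and near-infrared (NIR) reflectance fall with chlorophyll and canopy
loss but rebound under severe grazing as high-albedo soil dominates the
signal. Neither sensor alone separates all four management classes — no
grazing (NG), light (LG), moderate (MG) and severe (SG) — but their
responses are complementary, which is what this package exploits.

`grazspec` implements the full monitoring workflow on per-sample band tables
(three visible digital-number channels, four multispectral reflectance
channels) and on co-registered raster scenes: spectral-index fusion,
separability screening, automatic incremental feature selection (AIFS),
classification, and pixel-level mapping.

## Band normalization and the index registry

Visible digital numbers are converted to chromatic coordinates,
`r = R/(R+G+B)` etc., so brightness cancels and the visible features live on
a scale commensurate with reflectance before fusion. A zero channel sum
marks the sample invalid (`NA`); the package never substitutes a silent
zero or epsilon, because clamping would distort the index distributions
that the separability screen and the classifiers consume. Downstream
operations each declare how they treat `NA` (listwise removal with logged
counts in the statistics; row dropping with a warning in the selectors;
nodata pixels in the mapper).

The registry holds 24 indices in three families:

* 4 conventional visible-light indices (ExG, VARI, ExGR, RGBVI),
* 6 conventional multispectral indices (NDVI, GNDVI, SAVI, MSAVI, NDRE,
  EVI2),
* 14 purpose-built fusion indices (`idx1`–`idx14`) that mix chromatic
  coordinates with reflectance bands, e.g.
  `idx7 = (b − RE)/(b + RE)` and `idx9 = (b·NIR)/(r·g)`.

Decisions taken where the formulas left room:

* Visible-light indices are evaluated on chromatic coordinates by default
  (`rgb_mode = "raw"` switches to digital numbers). Normalization exists
  precisely to balance the two sources in fusion, so the normalized form is
  the default.
* ExGR is implemented in its standard literature form
  `ExG − (1.4·R − G)`; MSAVI in its standard form with the square root,
  `(2·NIR + 1 − sqrt((2·NIR+1)² − 8·(NIR − R)))/2`.
* SAVI's soil factor defaults to `L = 0.5`, the conventional intermediate
  vegetation-density value; it is an argument, not a constant.
* `idx14` compares NIR against the mean of the chromatic coordinates. Under
  simplex normalization that mean is the constant 1/3, making the index a
  monotone transform of NIR. It is implemented literally by default
  because that is what the formula says; `idx14_mode = "scaled"` offers the
  plausible alternative (mean of DN/255), which varies with brightness.

```{r registry}
table(index_registry()$family)
```

## Separability analytics

For screening, the package reports per-class means and variances, one-way
ANOVA with Tukey's HSD multiple comparisons (default familywise
`alpha = 0.05`), and the pairwise M-statistic

M = |x̄₁ − x̄₂| / √(s₁² + s₂²),

a unitless mean separation: M > 1 roughly means the class means sit more
than one joint standard deviation apart. Variances use the sample (n−1)
estimator — the definition leaves the denominator convention open, and the
n−1 form matches the ANOVA machinery used alongside. All six class pairs
are reported together with min/mean/max summaries, so both a "best pair"
and an "average" reading of a feature's separability are recoverable. M is
a univariate screen only: features with weak standalone M can still carry
complementary multivariate signal, which is exactly why selection is done
by the classifier-driven AIFS rather than by thresholding M.

## Automatic incremental feature selection

AIFS combines three ingredients:

1. **Ranking.** A random forest is grown on the fused matrix and each
   feature scored by the mean over trees of the out-of-bag error increase
   after permuting that feature (raw permutation importance). Candidates
   are visited in descending score order; ties keep column order.
2. **Correlation gate.** A candidate whose absolute Pearson correlation
   with any already-selected feature exceeds `rho_thresh = 0.8` is
   rejected as redundant, before any model is fit.
3. **Accuracy gate.** A surviving candidate is provisionally added and the
   stratified 5-fold cross-validated overall accuracy of a gate classifier
   is computed; the candidate stays only if accuracy strictly improves.

The gate classifier is configurable (`rf`, `svm`, `knn`) and defaults to a
random forest seeded like the ranking step, keeping the selection loop
consistent with the importance model. Folds are stratified and frozen once
per run, and each gate evaluation is seeded from the run seed and step
index, so `replay_aifs()` can re-derive every accept/reject decision from
scratch — the result object is an auditable trajectory, not just a feature
list. Two deliberate details: correlations are computed on the full matrix
handed to the selector (not fold-wise), which mirrors how the procedure is
used in practice but means the correlation screen sees all rows — callers
who want strict train-only selection should pass the training partition;
and zero-variance columns are dropped inside the gate fit, which makes the
selector provably invariant to constant features.

## Partitioning, classifiers, evaluation

**SPXY.** Train/test partitioning uses joint X–Y distances:
`d_xy = d_x/max(d_x) + d_y/max(d_y)`, Kennard–Stone selection seeded by the
mutually farthest pair, fully deterministic. Class labels enter the
Y-distance as ordered integer codes (NG=0 … SG=3), treating grazing
intensity as ordinal; a one-hot coding is available for a purely nominal
reading. 70% of samples go to training by default. Because SPXY picks
boundary-spanning points first, the test set is not class-balanced — that
is inherent to the method, not a bug.

**Models.** Three families with exhaustive grid search by stratified 5-fold
CV on the training partition, features z-scored with training statistics:

| family | grid |
|---|---|
| KNN | K ∈ {3,5,7,9} × metric ∈ {euclidean, manhattan, cosine}, votes weighted 1/d |
| RBF-SVM | kernel scale ∈ {0.1,0.5,1,2} × box constraint C ∈ {0.1,1,10} |
| RF | trees ∈ {100,200,300} × min leaf ∈ {1,5,10} |

The kernel scale s is translated to the RBF width as `gamma = 1/s²`
(the "kernel scale / box constraint" parameterization of the grids). KNN
resolves a zero-distance neighbor by majority vote among the coincident
points (infinite weight); grid ties go to the first combination in grid
order. Tuning folds default to 5 — the grid ranges are fixed by convention
but the tuning fold count is a package choice. Per-class 3·IQR outlier
removal is deliberately not applied by default: no removal rule is part of
the method's definition, and silent row deletion would complicate the
audit trail.

**Evaluation.** Confusion matrix (reference rows × predicted columns),
overall accuracy OA = trace/n, and Cohen's kappa
κ = (p_o − p_e)/(1 − p_e) with p_e = Σ row_i·col_i / n². κ is reported as
`NA` when p_e = 1.

## Mapping

`classify_raster()` computes the model's features per pixel and predicts a
class; any pixel with an undefined feature becomes nodata (code 255).
`mode_filter_3x3()` smooths the categorical map: each cell takes the modal
class of its 3×3 neighborhood (valid sub-window at edges, nodata never
votes). A mean or median is meaningless on class codes, so the filter is
modal by construction; ties keep the center value, which makes the filter
stable (idempotent on uniform maps, never inventing codes). ROI extraction
uses pixel-center containment (cell `[row, col]` centered at
`(col − 0.5, row − 0.5)`) with an even-odd polygon test; stratified random
extraction draws a fixed pixel count per class under the run seed. Band
stacks are plain in-memory arrays: the package expects co-registered
inputs and ships no resampling of its own beyond `stack_from_table()` for
round-tripping tables.

## The synthetic generator: what it emulates and what it does not

There is no deposited field dataset, so the generator is first-class
package code, not a test hack. The default scenario reproduces the study
design — 720 samples, 180 per class, four classes — and encodes the
qualitative band responses described above as class-conditional independent
truncated Gaussians (DN bands truncated to [0,255], reflectance to [0,1]):

```{r preset}
t(sapply(default_profiles(), function(p) p$band_means))
```

The sds are 12/12/10 DN for the visible bands and 0.015/0.015/0.02/0.025
for G/R/RE/NIR. These numbers are the package's own preset: they respect
the published qualitative orderings (visible rise-then-dip, green/red
rise, red-edge/NIR fall-then-rebound) and place the class overlap where
the science says it belongs — LG and SG nearly coincide in the visible
bands and are pulled apart by red/NIR, so fusion demonstrably helps. The
magnitudes are chosen to be realistic for sparse semi-arid canopies
(reflectance separations of 1–3 within-class sds), not fitted to any
published figure, whose numeric values are not printed. Scenarios can
append pure-noise and near-duplicate (|ρ| > 0.9) columns to exercise the
selector's two gates.

What the generator does **not** emulate: band-to-band correlation within a
class (unless a covariance matrix is supplied), mixed soil–vegetation
pixels, illumination gradients, shadows, stitching artifacts, or spatial
autocorrelation inside raster quadrants. Passing tests on this data
therefore demonstrates the correctness and internal consistency of the
algorithms — not field-level accuracy; accuracy numbers on synthetic
scenes are much higher than any UAV campaign would produce.

One generator seed drives everything through a documented per-stage
derivation (sample draws before raster draws), so tables and scenes are
jointly reproducible.

## Numerical choices and degenerate inputs

* Division by zero anywhere in an index yields `NA`, never a clamp.
* M with both variances zero: 0 for equal means, `NA` (with a warning) for
  unequal means — the statistic is genuinely undefined there.
* Zero-total-variance features are excluded from ANOVA rather than
  producing 0/0 F statistics.
* The importance sort is stable, so permutation-noise ties cannot reorder
  equally-scored features between runs.
* SPXY refuses an all-identical X (max distance 0) instead of dividing
  by zero.
* Truncated-Gaussian draws redraw out-of-range values, so a mean close to
  a physical bound slightly biases the realized mean toward the interior;
  the preset keeps means ≥ 3 sd from the bounds, where the effect is
  negligible.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full 720-sample design
for the end-to-end properties (selection audit, fusion-ordering checks,
64×64-pixel scenes) and down-scaled scenarios (15–60 samples per class)
for unit-level behavior; the null-calibration check uses 200 replicates of
a 4×15 one-feature design. These sizes give stable Monte-Carlo behavior
at interactive runtimes and are stated here as the package's reference
configuration.

## Known limitations

* Feature selection on the full matrix before splitting leaks test rows
  into the correlation screen (see above); the whole-matrix workflow is
  the default, the conservative train-only workflow is one
  `subset_rows()` away.
* The M-statistic assumes roughly symmetric unimodal within-class
  distributions; heavy tails inflate the denominator.
* `kappa` compares against chance agreement from the empirical marginals;
  with SPXY's unbalanced test sets it is not comparable across splits of
  different composition.
* No geospatial metadata (CRS, geotransform) is carried; inputs must be
  co-registered arrays.
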