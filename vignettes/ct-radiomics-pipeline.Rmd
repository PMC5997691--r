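---
title: "A CT radiomics pipeline for tumor marker status: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A CT radiomics pipeline for tumor marker status: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctradiomics)
```

## The problem

Thymidylate synthase (TS) is a DNA-synthesis enzyme and the main target of
pemetrexed; low TS expression predicts better outcomes under
pemetrexed-based chemotherapy in non-squamous non-small cell lung cancer,
and TS-negativity itself appears prognostic. TS status is assayed by
immunohistochemistry on biopsy tissue, which is invasive, semi-quantitative
and sensitive to tumor heterogeneity. This package implements a fully
tested version of a radiomics analysis that asks whether quantitative CT
features of the segmented tumor — together with clinical covariates — can
predict the binary TS label, and whether the label stratifies survival.

The pipeline has five analysis stages, each exposed as ordinary R
functions: (1) reading aligned CT image/mask pairs and applying the
five-lesion-per-patient cap; (2) extracting a fixed 60-feature panel per
lesion; (3) averaging lesions to patient level and screening each variable
against the label with univariate logistic regression; (4) a 10-fold
cross-validated random-forest prediction procedure with in-fold variable
selection, pooled out-of-fold probabilities, a single ROC AUC, and DeLong
comparison of competing models; and (5) Kaplan–Meier / log-rank survival
comparison between label groups. A synthetic phantom cohort generator
provides data with the statistical structure the analysis assumes, so every
stage is testable without patient data.

## The feature panel

The extractor emits exactly 60 named features per lesion
(`feature_manifest()` is the canonical list; a versioned YAML copy ships in
`inst/extdata/`):

* **19 whole-ROI histogram features** — mean, median, minimum, maximum,
  range, sd, variance, skewness, kurtosis, energy, entropy, RMS, IQR, MAD,
  UPP and the 2.5/25/75/97.5 percentiles of the HU distribution.
* **9 outer + 9 delta partition features** — the subset {mean, median, sd,
  minimum, maximum, skewness, kurtosis, energy, entropy} computed on the
  rim (`_outer`) and as core-minus-rim differences (`_delta`).
* **10 shape features** — volume, triangulated surface area,
  surface-to-volume, compactness, sphericity, convexity, maximum 3D
  diameter, elongation, density, mass.
* **11 GLCM features** — autocorrelation, contrast, correlation,
  dissimilarity, energy, entropy, homogeneity, cluster shade, cluster
  prominence, sum average, variance of the direction-averaged gray-level
  co-occurrence matrix.
* **2 size-zone features** — intensity variability and size-zone
  variability of the gray-level size-zone matrix.

Conventions that are fixed and worth knowing:

* Skewness and kurtosis use population (1/N) central moments; kurtosis is
  Pearson (non-excess), so a Gaussian scores 3. sd/variance are the sample
  (N−1) estimators. Percentiles interpolate linearly (R's type 7). MAD is
  the raw median absolute deviation (no 1.4826 consistency factor).
* Whole-ROI `energy` is the raw sum of squares (intensity-based, matching
  the common open-source convention) and `rms = sqrt(energy / N)`. In the
  partition panel, energy is the per-voxel mean square instead: the core
  and rim differ in size by a fixed 2:1 ratio by construction, so a raw sum
  would turn every energy delta into a volume artifact.
* Histogram entropy and UPP use 256 fixed-width bins spanning the sample's
  own [min, max]; UPP sums squared probabilities over bins with centers
  above 0 HU.
* `delta = inner − outer`. Inner values are intermediates and are not part
  of the 60.
* `density = mean HU + 1000` (≈ physical density in mg/ml for soft
  tissue), `mass = volume × density`. These are stated as definitions, not
  calibrated physics.
* On degenerate input (constant intensities, flat masks) the affected
  features are reported as missing *with a reason string*; keys are never
  silently dropped.

## ROI partitioning

The inner (core) / outer (rim) split is defined purely by volume: every
foreground voxel gets its exact Euclidean distance (in mm, anisotropy
aware) to the nearest background voxel, computed with the separable
lower-envelope distance transform; the `floor(N/3)` voxels closest to the
boundary form the rim and the rest the core, so the 1/3 : 2/3 split is
exact by construction. Distance ties are broken by lexicographic (z, y, x)
voxel order, which makes the partition bit-reproducible across platforms.
Disconnected ROIs are partitioned through one global distance field rather
than per component. Masks with fewer than 27 foreground voxels are
rejected: at that size the rim sub-ROI becomes too small for moment-based
features, the same reason small lesions are flagged "not analyzable" in
practice. Voxels outside the image grid count as background, so a mask
touching the grid edge still has a finite boundary distance.

## Texture matrices

GLCMs are built at 256 gray levels, discretized over the ROI's own
intensity range with fixed-width bins. All 13 unique offsets of the 3D
26-neighborhood (modulo sign) are accumulated separately, symmetrized,
normalized to unit sum, and averaged element-wise. A direction with no
valid voxel pair cannot be normalized and is skipped from the average (it
is an error only if *no* direction has a pair — for instance a single
isolated voxel). Feature formulas use 1-based bin labels; `0·log 0 = 0`,
and correlation of a zero-variance (single-level) matrix is reported as its
limit, 1.

The size-zone matrix uses 32 gray levels; zones are 26-connected components
of equal discretized level within the ROI. Intensity variability and
size-zone variability are the squared row- and column-marginal sums
normalized by the zone count — both equal 1 when the ROI is a single
uniform zone.

Both matrix builders are verified in the test suite against brute-force
nested-loop enumeration on random 8³ phantoms, exactly.

## Shape measurement

Surface area triangulates the 0.5-isosurface of the binary mask by
marching tetrahedra (6 tetrahedra per grid cell; with binary corner values
every edge crossing is a midpoint, so the mesh geometry per sign pattern is
a constant and the area reduces to a case count). Triangulating a binary
(staircase) surface systematically overestimates the area of the smooth
shape it digitizes — a digital sphere reads ~25% high — which depresses
sphericity/compactness below their continuum values; the values are
internally consistent and scale exactly with spacing, which is what the
downstream screening uses. Convexity is the foreground voxel count divided
by the voxel count of the digitized convex hull (incremental quickhull of
the foreground voxel centers, digitized by counting the grid centers it
contains), so convexity ≤ 1 with equality, up to digitization, for convex
shapes. Elongation is `sqrt(λ2/λ1)` of the coordinate covariance of the
foreground voxel centers in physical units. Planar or collinear masks have
no 3D hull; convexity is then missing-with-reason.

## Aggregation and screening

Patients contribute up to five lesions (the primary lung lesion always
retained; non-primaries ranked by longest diameter, ties by lesion id), and
the patient feature vector is the element-wise mean over the selected
lesions, excluding missing entries pairwise. Screening fits
`logit P(TS+) = β0 + β1 x` per variable by IRLS (tolerance 1e-8, max 50
iterations). Continuous predictors are standardized first, so odds ratios
are per SD — the original cohort's printed odds ratios are not per-unit
crude ratios and their scaling is not recoverable, so a declared, fixed
scale is the only honest choice. Two-level predictors are coded 0/1, which
makes the logistic MLE odds ratio equal the 2×2 cross-product ratio.
Complete separation is flagged (odds ratio withheld) rather than raised.
No multiplicity correction is applied by default, mirroring the original
analysis; Benjamini–Hochberg is available behind `adjust = "BH"`.

## Cross-validated prediction

`cv_predict()` implements the seven-step internal validation: a seeded
shuffle + round-robin split into 10 folds (sizes differ by at most one; a
label-stratified variant is available and recommended for small n), then
per fold: variable selection on the nine training folds, a 500-tree random
forest on the selected variables, and out-of-fold probabilities for the
held-out fold; all out-of-fold probabilities are pooled into a single ROC
curve whose AUC is the Mann–Whitney statistic (ties count one half).
Model AUCs computed on the same patients are compared with DeLong's
structural-component test; the test's variance estimate is identical to
the class-wise delete-one jackknife, and the suite asserts that equality
to 1e-10.

Variable selection is a simplified two-stage version of the
random-forest procedure of Genuer and colleagues:

1. *Thresholding.* 25 forests are grown with a pure-noise probe appended
   (a permuted copy of a randomly chosen real column). A variable survives
   only if its mean permutation importance exceeds the probe's mean by two
   standard errors of the probe mean — the shadow-feature significance
   margin familiar from Boruta. Without the margin, half of all pure-noise
   variables would outscore the probe by symmetry.
2. *Interpretation.* Survivors are ordered by importance and nested
   forests are grown adding one variable at a time; the selected model is
   the shortest prefix whose out-of-bag error is within one standard error
   of the minimum. A plain argmin is not used because on uninformative
   data the OOB curve is flat and the argmin lands uniformly along it,
   inflating the selected set.

If thresholding discards everything, the single top-importance variable is
used (flagged). The original procedure's CART-fitted importance threshold
is out of scope. Forest size defaults: 100 trees per selection forest, 500
for the prediction forest; all forests are reseeded deterministically from
the master seed through a counter, so `cv_predict()` is bit-reproducible
from `(X, y, seed)`.

## Survival

`km_estimate()` and `logrank_test()` wrap the survival package's
product-limit estimator and two-group log-rank test behind the pipeline's
interface, with the standard convention that events precede censorings at
tied times. The suite checks the log-rank statistic against a hand-built
risk-table enumeration and its type-I error by simulation.

## The synthetic cohort generator

`cohort_spec()` / `simulate_cohort()` emulate the structure of the
motivating 169-patient cohort: TS-positive fraction 85/169; age ~
Normal(60, 8) years and ever-smoking probability 0.5, entering the label
model with log-odds effects +0.25 per SD of age and +0.84 for smoking (the
log of the 2.32 crude odds ratio implied by the cohort's published smoking
split), with the intercept solved by bisection so the marginal positive
fraction matches the target; a lesion-count distribution on 1–5 with mass
(0.55, 0.25, 0.12, 0.05, 0.03), mean 1.76, close to the published mean of
1.75 lesions/patient; exponential overall survival at 0.04 events/month
baseline with hazard ratio 2.0 for TS-positive patients (TS-positivity is
the poor-prognosis state) and independent Uniform(0, 40 months) censoring.

Phantom lesions are sphere-like ellipsoids (axis perturbations normalized
to unit product so the volume stays at 4/3·π·r³ within digitization
error), radius 8–12 voxels, with a constant 60 HU core filling the inner
two thirds of the volume, a linear ramp to a 20 HU rim, 15 HU Gaussian
noise, and a low-HU tail: each voxel is replaced with probability
`tail_fraction` by a draw from Uniform[−900, −400] HU. The tail is an
air/necrosis surrogate and the mechanism by which the two groups differ in
texture: group means 0.02 (TS−) vs 0.05 (TS+), with per-lesion SD 0.02 so
lesions within a group are heterogeneous and group separation is partial
rather than trivial. A larger tail fraction makes skewness more negative
and kurtosis larger — the directions reported for TS-positive tumors — and
moves GLCM entropy jointly. All randomness flows from one master seed
through named sub-streams (clinical, lesions, phantoms, survival), so
cohorts are byte-identical under a fixed seed.

What the generator does **not** emulate: scanner point-spread and noise
correlation, slice-thickness anisotropy effects, contrast-phase variation,
realistic lesion morphology (spiculation, cavitation), or any genuine
biological coupling between texture and TS biology. Passing tests
demonstrate that the pipeline's machinery is correct and calibrated — not
that CT texture predicts TS expression in patients.

## Numerical choices and problem sizes

Calibration properties are checked by simulation at fixed seeds: DeLong
and log-rank type-I error at 2000 null simulations each (accepted at
0.05 ± 0.01); the null pooled CV AUC at n = 400 over 20 seeds, where the
*mean* over seeds must lie in [0.44, 0.56] — a per-seed requirement would
be mis-specified, since a single null AUC at n = 400 has sampling SD
≈ 0.029 and would leave the band in roughly half of correct runs;
selection recovery of a 1.5 SD effect among 20 noise variables over 50
replicates (≥ 90%); AUC monotonicity over effect sizes {0, 0.6, 1.2} SD at
n = 200 with 20 seeds per level; and log-rank power ≥ 90% at hazard ratio
2 with n = 300 over 200 simulations. The oracle-equivalence tests (GLCM,
size-zone, distance transform, DeLong-vs-jackknife, log-rank risk tables)
are exact to the stated tolerances. These problem sizes keep the whole
suite under ten minutes on one core while leaving the Monte-Carlo standard
errors well inside the accepted bands.

## Known limitations

* The exact identity of the original 60 features is not published beyond
  category counts and examples; this panel is a fixed, documented superset
  of every named feature, and renaming requires only the manifest.
* Marching-tetrahedra area of binary masks overestimates smooth surfaces
  (see above); no mesh smoothing is applied.
* The partitioning realization (distance-ranked peeling with lexicographic
  tie-breaks) is a documented design choice; the original work states only
  that the split is "purely by volume".
* Wavelet/filtered features, 2D per-slice variants, isotropic resampling,
  DICOM ingestion and Cox modeling are out of scope.
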