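# ctradiomics

An R package implementing an end-to-end CT radiomics pipeline for
predicting a binary tumor-marker label — thymidylate synthase (TS)
expression status in advanced lung adenocarcinoma — from segmented CT
lesions, and for relating the label to survival. TS is the main target of
pemetrexed; its status is normally assayed by immunohistochemistry on
biopsy tissue, so a noninvasive imaging surrogate is of real clinical
interest. The package is aimed at imaging scientists who want the whole
analysis chain as tested, reusable functions rather than a one-off script.

The pipeline:

1. **I/O and lesion selection** — NIfTI image/mask pairs with enforced
   grid alignment; at most five lesions per patient (RECIST-style), the
   primary lung lesion always retained (`read_lesion()`,
   `select_lesions()`).
2. **Feature extraction** — exactly 60 features per lesion
   (`extract_features()`, `feature_manifest()`): 19 whole-ROI histogram
   features; 9 outer-rim + 9 core-minus-rim (delta) features on a
   volume-based partition of the ROI into an inner core (2/3 of the
   volume) and outer rim (1/3), computed by exact Euclidean
   distance-to-boundary ranking (`partition_roi()`); 10 shape features;
   11 features of the gray-level co-occurrence matrix (GLCM, 256 gray
   levels, 13 directions averaged); 2 intensity size-zone features
   (32 gray levels, 26-connected zones).
3. **Aggregation and screening** — per-patient lesion means and
   univariate logistic regression of every variable against the label
   (`aggregate_patient()`, `screen_all()`); odds ratios are per SD for
   continuous variables.
4. **Cross-validated prediction** — 10-fold CV with in-fold random-forest
   variable selection (probe-thresholded permutation importance + nested
   out-of-bag minimization), 500-tree forests, pooled out-of-fold
   probabilities, one ROC AUC (`cv_predict()`, `pooled_roc_auc()`), and
   DeLong's test for correlated AUCs (`delong_test()`):

   AUC = P(score⁺ > score⁻) + ½·P(tie),  z = (AUC₁ − AUC₂)/√(V₁ + V₂ − 2C)

5. **Survival** — Kaplan–Meier curves and the two-group log-rank test for
   OS/PFS by label (`km_estimate()`, `logrank_test()`).
6. **Synthetic cohorts** — a seeded generator of clinical tables and 3D
   tumor phantoms whose texture (via a low-HU tail mixture) and clinical
   covariates differ between label groups, with exponential survival at a
   chosen hazard ratio (`cohort_spec()`, `simulate_cohort()`,
   `simulate_lesion_volume()`). The original patient cohort is not
   public; the generator provides data with the structure the analysis
   assumes so that every stage is verifiable.

## Worked example

Simulate a 40-patient phantom cohort, extract and aggregate features,
screen, cross-validate, and compare survival:

```r
library(ctradiomics)

spec <- cohort_spec(n_patients = 40, seed = 77)
coh  <- simulate_cohort(spec, images = TRUE)

# one lesion's feature vector
fv <- extract_features(coh$lesions[[1]])
fv
#> Radiomic feature vector (P0001 / P0001_L1): 60 features, 0 missing

# patient-level features: select <= 5 lesions, extract, average
by_pat <- split(coh$lesions, sapply(coh$lesions, `[[`, "patient_id"))
pvs <- lapply(by_pat, function(ls)
  aggregate_patient(lapply(select_lesions(ls), extract_features)))
feats <- data.frame(patient_id = names(pvs),
                    do.call(rbind, lapply(pvs, `[[`, "values")))
names(feats)[-1] <- feature_manifest()$name

scr <- screen_all(coh$clinical, feats)
head(scr[order(scr$p_value), c("variable", "odds_ratio", "p_value")], 3)
#>   variable odds_ratio  p_value
#> 15  energy     18.933 0.000758
#> 18     iqr     34.903 0.001615
#> 19     mad     32.059 0.002760

y  <- coh$clinical$ts_label
Xc <- data.frame(age = coh$clinical$age,
                 smoking = as.integer(coh$clinical$smoking == "ever"))
Xr <- cbind(Xc, feats[, c("skewness", "kurtosis", "glcm_entropy", "maximum_delta")])
folds <- make_folds(40, k = 5, seed = 7, stratify = y)
cv_c <- cv_predict(Xc, y, folds = folds, seed = 7, select = FALSE)
cv_r <- cv_predict(Xr, y, folds = folds, seed = 7, select_B = 10, select_num_trees = 50)
cv_r
#> 5-fold cross-validated prediction (n = 40, seed = 7)
#>   pooled out-of-fold ROC AUC: 0.992
#>   variables selected per fold: 1 1 1 2 3

delong_test(cv_r$probabilities, cv_c$probabilities, y)
#> DeLong comparison of correlated AUCs
#>   AUC A = 0.992, AUC B = 0.229
#>   z = 10.082, two-sided p = 6.651e-24

logrank_test(coh$clinical$os_time, coh$clinical$os_event, y)
#> Log-rank test (1 df)
#>   0: n = 21, observed 10, expected 14.47
#>   1: n = 19, observed 15, expected 10.53
#>   chi-square = 3.402, p = 0.06512
```

Reading the output: clinical covariates alone barely order this tiny
synthetic cohort (AUC 0.23 — worse than chance at n = 40), while the
texture features separate the groups almost perfectly (AUC 0.99): the
generator injects a deliberately strong texture contrast (group tail
fractions 0.02 vs 0.05) so the machinery's sensitivity is visible at demo
size. The log-rank test shows the expected survival disadvantage of the
TS-positive group (hazard ratio 2 in the generator) that is not yet
significant at n = 40. These numbers characterize the phantom generator,
not patients.

A thin command-line front end over the same functions ships in
`inst/scripts/radiomics-cli.R` (subcommands `extract`, `simulate`,
`screen`, `survival`).

## Methods

See the vignette (`vignettes/ct-radiomics-pipeline.Rmd`) for the model
and feature definitions, the partitioning and selection algorithms, every
numerical convention, what the phantom generator does and does not
emulate, and known limitations.
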