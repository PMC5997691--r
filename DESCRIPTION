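Package: ctradiomics
Title: CT Radiomics Pipeline for Tumor Marker Status Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end CT radiomics analysis pipeline for predicting a binary
    tumor marker status (thymidylate synthase expression) from segmented lung
    lesions. Implements a 60-feature extractor (whole-ROI histogram features,
    core/rim partition features with outer and delta panels, shape, gray-level
    co-occurrence matrix and intensity size-zone features), volume-based
    inner/outer ROI partitioning via an exact anisotropic Euclidean distance
    transform, per-patient lesion selection and aggregation, univariate
    logistic screening, a 10-fold cross-validated random-forest prediction
    procedure with in-fold variable selection, pooled out-of-fold ROC AUC and
    DeLong comparison of correlated AUCs, Kaplan-Meier and log-rank survival
    comparison, and a synthetic 3D tumor-phantom cohort generator for
    validating every stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    ranger,
    survival,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
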