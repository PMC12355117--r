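Package: phosphoSig
Title: Phospho-Protein Expression Signatures with Case-Cohort Weighted
    Survival Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives transcriptional signatures that estimate a continuous
    phospho-protein level (stability correlation filtering followed by
    elastic-net regression with cross-validation and held-out validation),
    scores cohorts against such signatures, performs centroid-score
    triple-negative breast cancer (TNBC) molecular subtyping with BL2
    reassignment and a configurable tumor-immune-microenvironment
    classifier, and analyses stratified case-cohort survival data with
    generalized Horvitz-Thompson inverse-probability weights (weighted
    Kaplan-Meier, weighted Cox proportional hazards with robust variance,
    subgroup interaction tests, Benjamini-Hochberg correction). A synthetic
    cohort generator reproduces the statistical structure these analyses
    assume, so the full pipeline runs end-to-end without access-controlled
    trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
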