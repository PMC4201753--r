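Package: plateletAD
Title: Platelet-Proteome Biomarker Screening and Composite Diagnostic
    Scores for Alzheimer's Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a two-stage (discovery/verification)
    differential-abundance screen of 2D-DIGE platelet proteome spot maps,
    composite diagnostic sum scores that branch on APOE epsilon-4 carrier
    status, Firth-penalized logistic regression, nonparametric ROC/AUC
    evaluation with least-squares cut-off selection, and multiplex
    protein-biochip processing (four-parameter-logistic calibration, ERK2
    loading-control normalization, and proteomic genotyping). A synthetic
    cohort generator reproduces the statistical structure of the platelet
    study (group sizes, genotype frequencies, planted effect sizes and
    abundance ratios) so the full pipeline can be exercised and tested
    without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    nortest,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
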