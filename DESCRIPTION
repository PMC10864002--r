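Package: ifnsig
Title: Interferon-Stimulated Neutrophil Signature Scoring and Biomarker Evaluation
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for constructing and evaluating interferon-stimulated
    neutrophil gene signatures as immunotherapy-response biomarkers.
    Provides single-sample gene-set enrichment scoring (binned-control
    module scores and a rank-ECDF random-walk enrichment score), bulk
    RNA-seq deconvolution by non-negative least squares against a
    signature matrix with group-mode profile imputation, a negative
    binomial model-based bootstrap for signature enrichment statistics,
    Mann-Whitney stratification tests, ROC/AUC with stratified bootstrap
    confidence intervals, and a synthetic-data generator with planted
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
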