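Package: ndmi
Title: Leukocyte-Resolved Blood DNA Methylation Markers of Glucocorticoid
    Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for blood DNA methylation as a
    pharmacodynamic marker of glucocorticoid (dexamethasone) exposure.
    Generates synthetic whole-blood methylomes as Dirichlet-weighted
    mixtures of beta-distributed cell-specific methylation for six
    leukocyte types; estimates leukocyte proportions by constrained
    reference-based deconvolution; screens CpGs for cell-type-specific
    differential methylation with exposure-by-fraction interaction models;
    trains sparse elastic-net exposure indices scored through a logistic
    link; and computes statistical power for detecting exposure differences
    in index scores as a function of neutrophil fraction, sample size, and
    cell-fraction variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    pROC,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
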