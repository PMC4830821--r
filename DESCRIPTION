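Package: panelROC
Title: Hierarchical ROC Scoring of Multi-Domain Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-detection modelling for multi-marker diagnostic panels
    organised into functional domains. Implements empirical ROC cutoff
    discovery per marker, dichotomous abnormality scoring, domain-level
    tallying with re-ROC threshold selection, and a model-level
    abnormal-domain-count detection rule, together with diagnostic odds
    ratios, prevalence-adjusted predictive values, logistic and locally
    weighted (lowess) risk regression on the abnormal-domain count,
    stratified k-fold cross-validation, median imputation, and Spearman
    correlation against external functional measures. Includes a
    calibrated synthetic case-control cohort generator so the full
    cascade can be exercised and validated without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
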