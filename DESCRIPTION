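Package: uqtriage
Title: Entropy-Based Uncertainty Triage for Ensemble Malignancy-Risk Predictions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uncertainty estimation and selective-prediction triage for
    ensemble classifiers of pulmonary nodule malignancy risk. Scores each
    nodule by the mean binary entropy (in bits) of its ensemble member
    probabilities, calibrates percentile cut-offs on a development cohort,
    splits cohorts into certain and uncertain groups, and evaluates
    discrimination per group: AUC with bootstrap confidence intervals,
    sensitivity at fixed specificity, DeLong variance and AUC-comparison
    tests, and size/type subgroup characterization. Includes a synthetic
    cohort generator emulating screening and clinical nodule populations so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
biocViews: Classification, Software, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
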