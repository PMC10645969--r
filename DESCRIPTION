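Package: specbiopsy
Title: Spectroscopic Liquid-Biopsy Classification with Nested Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation pipeline for serum ATR-FTIR
    liquid-biopsy diagnostics. Generates synthetic cohorts of patients with
    replicate infrared spectra carrying class-dependent biomolecular band
    effects, preprocesses spectra (windowing, rubberband or polynomial
    baseline correction, derivatives, normalization), and runs patient-level
    nested cross-validation with 70:30 outer resampling, inner fivefold
    hyperparameter and probability-threshold tuning targeted at a minimum
    sensitivity or specificity, and replicate consensus (maximum-vote)
    prediction. Provides ROC/AUC utilities, positive predictive value under
    assumed prevalence, per-patient detection-rate stratification by
    metadata, and wavenumber-resolved feature-importance aggregation with
    tentative biomolecular band assignments.
License: MIT
Encoding: UTF-8
Imports:
    ranger,
    glmnet,
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
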