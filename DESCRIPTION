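Package: respvar
Title: Respiratory Variability Analysis from Triaxial Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Breath-by-breath respiratory variability (RV) analysis for
    disorders-of-consciousness research. Conditions raw triaxial
    accelerometer recordings into a respiratory waveform (zero-phase
    Butterworth band-pass, moving average, rolling-median drift
    correction), segments breaths and extracts inspiratory/expiratory
    times, rate, I/E ratio and amplitude, and computes a time-domain RV
    metric suite (SD, CV, RMSSD, triangular index, Poincare SD1/SD2 and
    ellipse area) over 300-s windows. Group comparison adjusts metrics
    for confounders with a generalized additive model, then applies
    bootstrap resampling, Mann-Whitney U tests and
    Benjamini-Hochberg FDR correction. Prediction modules benchmark
    random forest, elastic net, SVM-RFE and PLS regressions of CRS-R
    scores, and three classification pipelines for clinical outcome. A
    synthetic-cohort generator with known ground truth makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    mgcv,
    glmnet,
    randomForest,
    e1071,
    mixOmics,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
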