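Package: s2screen
Title: Acoustic-Electrocardiographic Indices for Pediatric Atrial Septal
    Defect Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for wearable
    phonocardiogram-electrocardiogram screening of secundum atrial septal
    defect in children. Synthesizes synchronized two-channel recordings with
    embedded ground truth, applies band-pass filtering, artifact rejection
    and end-expiration gating, delineates ECG and heart-sound fiducials
    (R peaks, Q onsets, S1, and the A2/P2 components of S2), computes the
    five timing indices (S2 splitting, S1-S2, S1-S2/RR, EMAT, EMAT/RR), and
    reproduces the group-comparison and diagnostic-performance statistics:
    Student's t and chi-square tests, Pearson correlation, age-stratified
    interaction analysis, nonparametric ROC analysis with Youden cut-offs,
    Hanley-McNeil standard errors, cross-validated and bootstrap
    bias-corrected AUC, and multivariable logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
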