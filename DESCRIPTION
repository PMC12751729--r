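Package: scdEEG
Title: Spectral, Network and Machine-Learning Analysis of Resting-State
    EEG for Amyloid Stratification in Subjective Cognitive Decline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing 19-channel resting-state EEG cohorts in
    preclinical Alzheimer's disease research. Implements epoch-based
    preprocessing (zero-phase band-pass filtering, amplitude-threshold
    artifact rejection, random selection of artifact-free 2-s epochs),
    Welch relative band power in the five classical bands, weighted
    phase-lag index (wPLI) functional connectivity, weighted graph metrics
    (clustering coefficient, node strength, global efficiency) under
    proportional thresholding, the group-comparison statistics used in
    amyloid-stratified cohort studies (pooled-variance t tests with
    Cohen's d, chi-square tests, ANCOVA with partial eta squared,
    age-adjusted bootstrapped partial correlations), and an imbalance-aware
    interpretable classification framework (AdaBoost on decision stumps,
    sequential forward feature selection, Borderline-SMOTE inside
    stratified cross-validation, permutation significance, exact Shapley
    attributions). A parameterised synthetic-cohort generator with planted
    spectral and connectivity effects makes the whole pipeline testable
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
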