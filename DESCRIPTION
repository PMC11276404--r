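Package: cystscore
Title: Automated Segmentation and Scoring of Pulmonary Cysts in Thoracic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the cyst burden in cystic lung disease from thoracic
    CT volumes. Implements a fully automatic, calibration-adaptive pipeline
    that isolates the lungs and large airways, derives location-specific
    attenuation thresholds from the surrounding air, the airway lumen and
    the local parenchyma, segments the cysts and reports the cyst score
    (percentage of lung volume occupied by cysts), alongside the standard
    fixed-threshold (-940 HU) semi-automatic baseline. Includes a seeded
    synthetic thoracic CT phantom generator with ground-truth masks,
    longitudinal rate-of-change computation over patient visits, and the
    agreement statistics used to validate automated scoring against the
    standard method: Bland-Altman limits of agreement, absolute-difference
    summaries, Welch's t-test, the two-sample F-test, Pearson correlation
    with pulmonary-function tests and Williams' test for two dependent
    correlations sharing one variable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
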