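Package: oncospectra
Title: Infrared Molecular Fingerprinting of Blood-Based Liquid Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric analysis pipeline for liquid-phase Fourier-transform
    infrared (FTIR) absorption spectra of blood serum and plasma: water-displacement
    baseline correction against a measured water reference, spectral truncation and
    silent-region masking, L2 vector normalization and optional Savitzky-Golay
    second derivatives; spectral quality control with a local outlier factor (LOF)
    implementation; covariate-balanced case/reference cohort construction by optimal
    pair matching on the Mahalanobis distance within propensity-score calipers;
    repeated stratified cross-validated linear support-vector-machine evaluation with
    ROC/AUC, optimal operating points and multiclass confusion summaries; and
    per-wavenumber group statistics (differential fingerprints, Student t p-values,
    Mann-Whitney AUC curves, effect sizes, area under the absolute differential
    fingerprint, PCA site checks). Includes a synthetic serum-spectra cohort
    generator with known ground truth so every stage is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC
Config/testthat/edition: 3
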