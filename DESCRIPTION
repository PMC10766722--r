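Package: allerquant
Title: Multiplexed MRM Quantification of Allergenic Food Proteins with
    Uncertainty Budgets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-acquisition analysis pipeline for multiplexed targeted
    LC-MRM quantification of allergenic food proteins in complex matrices
    such as chocolate. Provides stable-isotope-dilution calibration with
    matrix-matched and standard curves, statistical matrix-effect testing
    (F-screening of regression variances and pooled-variance slope t-test),
    calibration-based limits of detection and quantification with three
    alternative standard-deviation estimators, experimentally derived
    protein conversion factors from discovery proteomics intensity tables,
    conversion of peptide concentrations to total-allergenic-food-protein
    reporting units, a five-contributor GUM-style measurement-uncertainty
    budget with expanded uncertainty, repeatability and intermediate
    precision with variance-component decomposition, spike-recovery
    estimation, and compliance assessment against published allergen
    reference-dose schemes. A synthetic-data module generates calibration,
    incurred-sample, recovery and discovery datasets with the variance
    structure the analysis assumes, so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
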