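Package: ftdindex
Title: Regional MRI Atrophy Indices for Frontotemporal Dementia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes three volumetric MRI biomarkers for the differential
    diagnosis of frontotemporal dementia from per-subject regional
    brain-volume tables: the anterior vs. posterior index (API), the
    asymmetry index (ASI), and the left temporal pole index (TPL).
    Provides the supporting head-size/age/sex normalization chain,
    data-driven region weighting with negativity clamping, z-score
    calibration against a non-FTD reference population, classification at
    a fixed-specificity cutoff, ROC/AUC evaluation with diagnostic
    likelihood ratios, leakage-safe stratified cross-validation,
    hierarchical clustering of atrophy subtypes with FDR-corrected
    region-wise contrasts, and a synthetic memory-clinic cohort simulator
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
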