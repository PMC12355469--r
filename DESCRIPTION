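Package: RamanEry
Title: Raman and SRS Chemometrics for Erythroid Differentiation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectral-analysis toolchain for detecting drug-induced
    erythroid differentiation from hyperspectral Raman and stimulated Raman
    scattering (SRS) images of single cells. Provides constrained MCR-ALS
    image unmixing with non-negativity and a contribution-contrast step,
    OPLS-DA single-spectrum classification with VIP scores, group-aware
    cross-validation, permutation testing and ROC analysis, spectral-phasor
    segmentation of hyperspectral SRS cubes, and a fast two-marker
    ratiometric classifier (lipid-to-protein ratio and an alkyne
    mitochondrial probe band) with ROC-calibrated quadrant thresholds. A
    synthetic-data module generates endmember libraries, hyperspectral cell
    phantoms and labeled single-cell cohorts with ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    pracma,
    tiff,
    EBImage,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
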