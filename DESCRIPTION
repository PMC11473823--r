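Package: reims
Title: Multi-Site REIMS Lipidomic Classification of Breast Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Preprocessing, classification and variability analysis for rapid
    evaporative ionization mass spectrometry (REIMS) tissue spectra. Implements
    lockmass correction against continuously infused leucine-enkephalin,
    fixed-grid binning with total-ion-count normalization, PCA/LDA tissue
    classification with site- and patient-level cross-validation and a 5-SD
    outlier rule, cosine-similarity and KNN-based inter-site variability
    metrics, sparse (l1) feature selection, fatty-acid channel extraction with
    omega-6 ratio analysis, and a Gaussian channel (median/SD) subtype
    classifier. Ships a synthetic REIMS cohort generator emulating the
    adipose/tumor lipid contrast, site effects and cautery-mode differences of
    multi-centre intraoperative studies, for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml
Config/testthat/edition: 3
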