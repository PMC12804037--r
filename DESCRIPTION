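Package: tsrquant
Title: Automated Tumor-Stroma Ratio Quantification from Tissue Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated tumor-stroma ratio (TSR) quantification from
    multi-class tissue segmentation label masks. Implements a sliding-window
    region-of-interest engine with composition and four-quadrant eligibility
    tests, hotspot (maximum-stroma) TSR extraction, artifact exclusion,
    data-driven cut-off derivation (Youden index on ROC at a survival horizon;
    maximally discriminative log-rank scan), Kaplan-Meier/Cox survival
    stratification, and synthetic mask/cohort generators with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    survival,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
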