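Package: kcpachy
Title: Corneal Thickness Profiling and Keratoconus Staging from AS-OCT
    Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Normal-line pachymetry and keratoconus staging analysis for
    anterior-segment OCT B-scans. Provides a synthetic corneal-phantom
    generator with analytically known boundary geometry and thickness,
    sub-pixel boundary extraction from label masks or grayscale renders,
    surface-normal epithelial and corneal thickness measurement over a
    6 mm region of interest (40 samples every 0.15 mm), 20-zone cohort
    statistics (group means with 95% confidence intervals, one-way ANOVA,
    Welch t-tests, per-zone thickness-versus-stage trends), thickness
    ectasia indices with two-class linear discriminant screening and
    ROC/AUC evaluation, and segmentation-quality metrics (Dice, IoU,
    sensitivity, specificity, thickness error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
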