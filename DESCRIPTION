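Package: kyphofat
Title: Trunk Muscle Fat Quantification and Supine Kyphosis Analysis from CT
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies intramuscular fat (muscle-fat%, the percentage of
    voxels below -20 HU) and muscle volume within 3D muscle segmentations on
    CT, computes supine thoracic Cobb angles from endplate geometry, assesses
    multi-rater reliability with ICC(2,k), bootstrap confidence intervals and
    Bland-Altman analysis, applies confounder-exclusion rules, and correlates
    muscle-fat% with kyphosis. Includes a synthetic CT phantom and cohort
    generator with known ground truth so the full pipeline is exercisable
    without any external imaging data, plus reference implementations of
    segmentation agreement metrics (Dice, compound Dice + cross-entropy
    loss) and minimal NIfTI-1 input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
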