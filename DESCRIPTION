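Package: kbpaudit
Title: Knowledge-Based Plan Auditing for VMAT Prostate Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based dose-volume metrics, target-coverage indices
    (Paddick conformity index, homogeneity index), and constraint-template
    auditing for radiotherapy treatment plans, together with a
    knowledge-based planning (KBP) layer: geometric predictors (organ at
    risk / target overlap fraction, centre-of-mass distance,
    overlap-volume product) are linked to achievable dose metrics by
    simple linear models, and new plans are flagged against 95% prediction
    intervals. Includes before/after cohort comparison with the
    Mann-Whitney test, a synthetic pelvic phantom and cohort generator for
    validation, a portable plan-bundle text format, a minimal DICOM RT
    Dose / Structure Set reader, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
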