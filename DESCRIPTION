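Package: dcmmonitor
Title: Longitudinal Monitoring of Degenerative Cervical Myelopathy with
    Quantitative MRI and Clinical Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measurement-error-based detection of myelopathic progression in
    non-operatively managed degenerative cervical myelopathy (DCM). Turns
    per-slice spinal-cord quantitative MRI metrics (cross-sectional area,
    fractional anisotropy, magnetization transfer ratio, T2*-weighted WM/GM
    signal ratio) into age-corrected region summaries, tests longitudinal
    change against a test-retest noise null (z-scores with SD = sqrt(2)*SEM
    and an unweighted composite referred to a t distribution), classifies
    progression on clinical batteries (mJOA, percent-change rules) and
    anatomical MRI, compares the diagnostic accuracy of the competing
    monitoring methods (Wilson continuity-corrected intervals, Fisher exact
    tests, Youden's index), and applies a surgical decision algorithm. A
    synthetic-cohort generator with the same noise structure supports
    calibration and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
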