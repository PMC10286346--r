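Package: spascreen
Title: Development and Validation Pipeline for a Spondyloarthritis
    Screening Questionnaire
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the full statistical workflow used to develop and
    validate a short patient-reported screening questionnaire for
    spondyloarthritis (SpA) in a three-group case-control design: per-item
    contingency-table screening (Pearson chi-square / Fisher exact),
    factorability diagnostics (Kaiser-Meyer-Olkin index, Bartlett test of
    sphericity), principal-component extraction with varimax rotation,
    reliability- and validity-based item reduction (Cronbach's alpha,
    multitrait scaling success), derivation of a merged referral scale and
    its cutoff, and ROC-based screening performance with Hanley-McNeil
    confidence intervals.  A seeded latent-trait generator produces
    synthetic three-group cohorts with planted axial and peripheral item
    blocks so every stage of the pipeline can be exercised and tested
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
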