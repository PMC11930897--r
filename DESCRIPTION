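Package: lungrads
Title: Risk Stratification of Pure Ground-Glass Pulmonary Nodules with
    Lung-RADS Rule Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule engines for categorising pure ground-glass pulmonary
    nodules (pGGNs) under Lung-RADS 1.0, Lung-RADS v2022, and the
    complementary cLung-RADS v2022 system that grades nodules by the
    nodule-vessel relationship (GVR types I-IV) in addition to diameter.
    Includes the full diagnostic-accuracy toolkit used to compare such
    systems against pathology: confusion-matrix metric panels (recall,
    precision, accuracy, F-beta, Matthews correlation), tie-corrected
    ordinal ROC AUC with DeLong variance and paired DeLong tests,
    inter-rater ICC(2,1), a seeded synthetic screening-cohort simulator
    with closed-form calibration to target confusion matrices, and a
    command-line evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
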