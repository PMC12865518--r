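Package: resectability
Title: Multimodal Imaging Prediction of Tubo-Ovarian Cancer Resectability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired diagnostic-accuracy studies of
    preoperative resectability assessment in advanced tubo-ovarian carcinoma.
    Classifies per-patient site-involvement assessments (ultrasound, CT,
    whole-body diffusion-weighted MRI, surgical exploration) into
    resectable/non-resectable predictions via the eight ESMO-ESGO
    non-resectability criteria, scores each modality against the surgical
    outcome reference standard (sensitivity, specificity, predictive values,
    accuracy, F-beta, single-operating-point AUC, with Wilson and DeLong-type
    confidence intervals), tests non-inferiority of one modality against
    another on paired data (correlated AUCs and paired F1 scores, analytic
    and bootstrap variance engines), computes Obuchowski-McClish sample sizes
    for correlated-AUC non-inferiority designs, and simulates synthetic
    cohorts with the paired three-modality structure needed to validate every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
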