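Package: raclaims
Title: Claims-Based Effectiveness Algorithm for Rheumatoid Arthritis
    Medications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies rheumatoid-arthritis medication treatment episodes as
    effective or not from administrative pharmacy and medical claims, using a
    rule set built on medication adherence (medication possession ratio and
    infusion-schedule counts), biologic switching or addition, new nonbiologic
    DMARD starts, biologic dose escalation, glucocorticoid joint injections,
    and oral glucocorticoid initiation or dose increase. Provides the clinical
    gold standard based on DAS28/CDAI disease activity from registry visits,
    new-user treatment-episode construction, diagnostic-test validation
    (PPV, NPV, sensitivity, specificity with exact binomial confidence
    intervals), outcome-misclassification bias analysis, and a synthetic
    claims-cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
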