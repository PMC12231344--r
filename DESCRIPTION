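Package: comorisk
Title: Comorbidity Risk Between Chronic Physical Illness and Mental
    Health Disorders from Longitudinal Admission Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the comorbidity risk between chronic
    physical illnesses and mental health disorders from longitudinal
    hospital admission records coded in ICD-10. Implements a full
    pipeline: normalization of diagnosis codes and mapping to chronic
    physical and mental disease categories; cohort cleaning with an
    auditable record funnel; conversion of chronologically ordered
    admissions into temporally labeled classification instances; a bank
    of four tree-ensemble classifiers (random forest, extremely
    randomized trees, histogram gradient boosting, and regularized
    gradient boosting) whose top-10 feature-importance consensus
    nominates risk diseases; and pairwise comorbidity-intensity tables
    (relative risk and phi coefficient) stratified by sex and age band.
    A seeded synthetic cohort generator with planted pairwise
    comorbidity structure supports validation when real electronic
    health records are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
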