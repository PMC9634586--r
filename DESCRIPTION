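Package: bzrascreen
Title: Detecting Hazardous Benzodiazepine-Receptor-Agonist Use from
    Prescription Dispensing Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs individual-level drug exposure from out-patient
    prescription dispensing records for benzodiazepines and Z-drugs.
    Doses are converted to diazepam milligram equivalents (DME) and
    accumulated into per-patient daily dose arrays over a study year,
    from which windowed dose maxima and gap-tolerant continuous-use
    episodes are derived. Rule-based classifiers flag overdose use
    (90-day window average above 40 DME/day), long-term use (continuous
    episodes reaching 90 days with gaps of up to 3 days bridged),
    hazardous use (the conjunction of both) and over-indication use
    (no recorded diagnosis matching an approved indication of any
    dispensed drug). Includes cohort descriptive statistics with
    classical group tests, a hospital random-intercept regression of
    hazardous use on patient covariates, and a seeded synthetic
    prescription-record generator with constructively planted user
    archetypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
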