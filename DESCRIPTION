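Package: pvscreen
Title: Disproportionality Signal Screening for Spontaneous Adverse Event
    Report Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds drug-event 2x2 contingency tables from JADER-dialect
    spontaneous adverse event report extracts (DEMO/DRUG/REAC/HIST tables
    keyed by case identifier) and screens them with three disproportionality
    statistics: the reporting odds ratio with Woolf confidence interval, the
    proportional reporting ratio with Yates-corrected chi-square, and the
    Bayesian confidence propagation neural network information component.
    Includes cohort filtering (sex, suspected-drug participation, reporting
    window), composite MedDRA preferred-term event sets, a synthetic report
    generator with configurable true odds ratios for validation, and a
    reconstruction harness that back-solves unprinted contingency cells from
    published summary rows so published screens can be reproduced and audited.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
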