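Package: chipseek
Title: Identifying Microchip Implantation Events in Free-Text Veterinary
    Patient Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding and validating companion-animal microchip
    implantation events in the free-text examination fields of primary-care
    veterinary electronic patient records (EPRs). Provides microchip-field
    validation (15-digit Australian format), case-insensitive substring
    search with term ranking and overlap analysis, a rule-based classifier
    for the reasons a search term appears in a record, positive predictive
    value and Yates-corrected contingency statistics, continuity-corrected
    two-proportion sample-size calculation, age-at-implantation summaries,
    record linkage of duplicated microchip numbers across patient IDs, and
    a seeded synthetic EPR corpus generator with ground-truth labels for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
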