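Package: meningrisk
Title: Integrated Risk Stratification of Meningiomas from Methylation-Array
    Copy Number and CNS WHO Grade
Version: 0.1.0
Authors@R:
    person("Queen Square", "Neuro-Oncology Informatics", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools to compute the integrated molecular risk score for
    meningiomas from CNS WHO histological grade, methylation family and
    chromosome-arm copy number losses. Includes an arm-level loss caller for
    log2 copy-number segments exported from methylation arrays (IGV SEG
    dialect), a rules engine for the 2021 CNS WHO meningioma grading
    criteria, the additive model score with low/intermediate/high risk
    binning, cohort-level cross-tabulation reports, and a seeded synthetic
    cohort simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
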