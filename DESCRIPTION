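Package: emspop
Title: Period-Over-Period Surveillance of Opioid Overdose EMS Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for syndromic surveillance of opioid overdoses from
    deidentified emergency medical services (EMS) treatment records.
    Reconstructs quasi-unique EMS runs from treatment-level rows, classifies
    opioid-relatedness from clinical impression fields, counts weekly outcomes
    (opioid-related runs, naloxone administrations, multiple naloxone
    administrations), and measures change in a focal window with a
    period-over-period statistic placed within a sliding-window quasi-control
    distribution of historical changes. Includes Welch unequal-variances tests,
    classical seasonal decomposition diagnostics, a seeded record-level
    synthetic data generator, and Table- and Figure-style report builders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
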