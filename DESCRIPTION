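Package: pvsignal
Title: Disproportionality Signal Mining for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous adverse-event report
    databases distributed as FAERS-style quarterly ASCII extracts. Reads the
    DEMO/DRUG/REAC/OUTC tables, deduplicates versioned case reports,
    selects primary-suspect drug cohorts against a synonym lexicon, flags
    events with an SMQ-style preferred-term set, and mines drug-event signals
    with the reporting odds ratio (Woolf 95% interval) and the Multi-item
    Gamma Poisson Shrinker empirical-Bayes geometric mean (EBGM/EBGM05).
    Includes a synthetic report generator with planted relative reporting
    rates so every stage is testable without downloading the real corpus,
    plus clinical characteristic and annual-trend summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
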