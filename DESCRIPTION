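Package: cprenrich
Title: Absolute Abundance, Growth and Oxygen-Related Metabolic Profiling of
    CPR Bacteria in Enrichment Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 16S rRNA amplicon time series from
    groundwater enrichment incubations with a focus on bacteria of the
    candidate phyla radiation (CPR, Patescibacteria). The package anchors
    relative amplicon abundances to total 16S rRNA gene copy numbers from
    quantitative PCR to estimate absolute abundances per amplicon sequence
    variant (ASV), fits exponential growth rates and doubling times by
    log-linear regression, assesses in-silico coverage of degenerate PCR
    primers under mismatch and 3'-anchor rules, maps genome annotations onto
    an oxic/anoxic/augmented metabolic reaction classification, filters
    compositional co-occurrence networks for CPR-containing edges, and
    screens supplement associations and CPR community diversity. A
    synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    vegan,
    Biostrings,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
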