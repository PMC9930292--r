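Package: poipanel
Title: Gene-Panel Variant Interpretation for Premature Ovarian Insufficiency Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interprets targeted gene-panel sequencing results for cohorts of
    women with premature ovarian insufficiency (POI). Provides HGVS-based
    consequence categorization, population-frequency rarity filtering, a
    simplified ACMG-style pathogenic/likely-pathogenic classifier,
    per-patient causality assignment under gene-specific inheritance modes
    (including compound-heterozygote, MSH4-MSH5 digenic-heterodimer, and
    oligogenicity calls), cohort-level prevalence and enrichment statistics,
    and a synthetic-cohort generator with planted causal genotypes for
    end-to-end validation. Ships a 28-gene POI panel and a fully curated
    72-patient example cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
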