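Package: jhminer
Title: Rule-Based Extraction of Population Characteristics from Justice
    Health Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts four population characteristics (age, sex,
    nationality, and offender type) from bibliographic abstracts in the
    justice health / epidemiological criminology literature using
    gazetteer dictionaries and semifrozen lexical-pattern rules.
    Standardizes raw mentions to canonical categories (Australian Bureau
    of Statistics age groups, five sex categories, nationality demonyms,
    a two-level offender-type taxonomy), evaluates extraction at the
    abstract level (per-characteristic, macro- and micro-averaged
    precision, recall and F1), and computes descriptive gap analytics:
    characteristic coverage, age-group and offender-type distributions,
    sex-proportion time series, and crude versus prisoner-population-
    adjusted country rankings. Includes readers for MEDLINE flat format
    and PubMed XML, and a synthetic-corpus generator with known gold
    annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
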