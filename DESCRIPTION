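Package: termtrends
Title: Temporal Terminology Trend Analysis for Conference Abstract Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to track how controlled-vocabulary terms rise and fall
    across the years of a recurring scientific conference. The pipeline
    ingests delimited tables of abstracts, cleans and tokenizes the text,
    discovers candidate multiword terms by document-frequency ranking,
    applies a curated terminology corpus with variants and acronyms grouped
    into mutually exclusive categories, and computes per conference-year
    frequency metrics: absolute term frequency, term frequency normalized by
    the year's vocabulary size, relative term frequency per million words,
    abstract-level and year-level document frequency, inverse document
    frequency, TF-IDF, and three-point moving averages. A synthetic corpus
    generator with planted term occurrences provides exact ground truth for
    every stage. Outputs are tidy tibbles ready for plotting as trend lines
    or word clouds.
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
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
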