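Package: seriesfinder
Title: Semantic Retrieval and Benchmarking of Gene-Expression Series Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds additional relevant gene-expression data series given a
    small set of known-relevant ones. Free-text series descriptions (title,
    summary, overall design) are cleaned, optionally split into overlapping
    character chunks, and embedded as fixed-dimension numeric vectors; the
    reference embeddings are averaged and candidate series are ranked by
    cosine similarity. Includes readers for a minimal SOFT-dialect key-value
    metadata format and canonical JSON/TSV tables, the series inclusion
    filters used for human expression-profiling studies, a deterministic
    hashed bag-of-words embedding backend plus a plug-in contract for
    external embedders, a word-overlap baseline, and a full evaluation
    harness (reference/comparison splits, imbalance subsampling, average
    precision, recall at n, cross-condition model ranking) together with a
    synthetic condition-annotated corpus generator so the whole pipeline is
    testable without network access.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
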