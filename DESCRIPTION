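Package: mdlink
Title: Extracting Microbe-Disease Associations from Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for mining microbe-disease associations
    from biomedical sentences. Entities are tagged by longest-match dictionary
    lookup, candidate microbe-disease pairs are classified with a hierarchical
    bidirectional LSTM with entity-based attention, and relation-describing
    words are extracted by an ensemble of constituency tree-pattern matching
    and dependency-tree lowest-common-ancestor rules scored with a Bayes
    confidence model. Downstream tools aggregate extracted triplets into a
    microbe-disease association table and a Jaccard disease-similarity
    network. A deterministic synthetic-corpus generator with gold parse trees
    supports end-to-end evaluation without external parsers or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    igraph,
    generics,
    ggplot2,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
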