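Package: nporigin
Title: Classifying Natural Product Origin from Molecular Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a natural product originates from a plant, a
    fungus, or a bacterium using only its molecular structure. Implements
    record curation for natural-product databases (DOI filtering, taxonomy
    keyword resolution, SMARTS-based glycoside/peptide flags, descriptor
    binning), the MinHashed atom-pair (MAP4) fingerprint with comparator
    encodings, a one-vs-rest support vector machine over a custom
    match-fraction kernel with Platt-scaled class probabilities, evaluation
    by balanced accuracy, Matthews correlation and F1, and a chemical-space
    map built from an LSH forest, k-nearest-neighbor graph and minimum
    spanning tree layout. Ships a seed-reproducible synthetic natural-product
    generator so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    Rcpp,
    igraph,
    jsonlite,
    kernlab,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
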