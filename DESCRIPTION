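Package: taxmapr
Title: Multi-Reference Scientific Name Mapping for Taxonomic and Natural
    Product Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves scientific-name strings (including typographical
    errors, Latin-inflected drug names, strain-coded names and vernacular
    variants) to taxon identifiers in a chosen taxonomic reference.
    Several references (NCBI taxdump and Darwin-Core-style taxon tables)
    are consulted simultaneously, so that synonym relationships and
    phylogenetic lineages recorded in one reference can rescue queries
    that are absent from another. A six-stage mapping cascade combines
    exact matching, cross-reference synonym recursion, lineage-aware
    nearest-taxon assignment, Damerau-Levenshtein spelling correction
    with genus-block pruning, Latin declension reconstruction and partial
    mapping, each outcome labelled with a status code. Also included:
    cross-reference discrepancy diagnostics (canonical/synonym disputes,
    hemihomonyms, rank disagreements), deterministic synthetic reference
    and typo generators for end-to-end testing, and a pipeline that
    standardises and integrates species-compound occurrence tables from
    natural-product databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
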