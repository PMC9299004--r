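Package: domtopics
Title: Domain-Topic Models of Document-Term Graphs via Nested Stochastic
    Block Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous hierarchical clustering of documents (domains) and
    terms (topics) from the bipartite document-term incidence graph, using a
    nested degree-corrected stochastic block model fitted by minimum
    description length.  Supports chained models that cluster document
    metadata (years into periods, countries into groups) against a frozen
    domain hierarchy, information-theoretic block characterisation (nested
    specificity and nested commonality), domain-topic tables, interactive
    map exports, prevalence-shift and bump-chart analyses, together with
    minimal language-independent corpus preprocessing (tokenisation, bigram
    collocation merging) and a planted-structure synthetic corpus generator
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    optparse
Config/testthat/edition: 3
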