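Package: dyspath
Title: Dysregulated Pathway Detection in Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects minimal connected subnetworks ("dysregulated pathways")
    of a protein interaction network in which at least k genes are
    dysregulated in every case sample except up to l outlier cases.
    Provides per-gene dysregulation calling against a normal model fitted
    to control samples, a minimal-radius connected set-multicover solver
    built on rooted breadth-first radius scanning and greedy expansion,
    hub-hiding and clean-up heuristics, permutation-based empirical
    significance with data-driven selection of k, and a synthetic-data
    generator with planted pathways for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
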