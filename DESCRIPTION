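Package: probdom
Title: Critical Node Classification for Probabilistic Dominating Set
    Control of Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for controllability analysis of undirected networks whose
    edges carry interaction probabilities. Finds probabilistic minimum
    dominating sets (every node is a driver or is covered by driver
    neighbours with combined success probability above a threshold) with an
    exact branch-and-bound solver, and classifies every node as critical,
    intermittent or redundant across all optimal solutions, using graph
    reduction rules to shrink the instance before exact search. Includes
    construction of age-specific dynamic weighted protein networks from
    microarray detection calls and a static interactome, a weighted
    scale-free benchmark network generator (power-law degree sequence,
    Havel-Hakimi realization, degree-preserving edge swaps), and gene-set
    enrichment statistics over the control categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
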