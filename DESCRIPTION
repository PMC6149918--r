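Package: mogacsm
Title: Multi-Objective Discovery of Condition-Specific Network Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects condition-specific modules in a collection of weighted
    undirected networks that share one vertex set (a multiplex network), one
    layer per biological condition. A locus-based genetic algorithm with
    NSGA-II style nondominated sorting simultaneously maximizes Newman-Girvan
    modularity in the target condition's layer and minimizes it in every other
    layer, so the returned gene sets are densely interconnected only under the
    target condition. Includes the planted-partition benchmark generator used
    to characterize the method, a degree-preserving permutation test with
    Benjamini-Hochberg correction for module significance, expression-derived
    module activity features, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
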