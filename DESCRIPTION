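Package: antnets
Title: Comparative Analysis of Ant Social Interaction Networks
Version: 0.1.0
Authors@R:
    person("Ant", "Networks Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for building weighted social interaction networks from
    automated tracking of ant colonies and for characterising their
    structure. Includes capsule-overlap interaction inference from
    detection records, soft two-community detection by symmetric
    nonnegative matrix factorisation with soft-modularity scoring,
    degree-preserving rewiring null models and permutation tests,
    social-maturity and division-of-labour statistics, hexagonal-grid
    90% home ranges, queen-worker encounter kinetics, and a synthetic
    colony generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
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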