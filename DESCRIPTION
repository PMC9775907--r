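Package: motifResilience
Title: Dynamical Resilience of Mutually Repressing Motifs Embedded in
    Random Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how toggle-switch and toggle-triad motifs lose
    their canonical multistable dynamics when embedded in larger random
    gene regulatory networks. Generates random directed signed networks
    with an embedded motif, simulates ensembles of randomized-parameter
    ordinary differential equation models with shifted-Hill regulation
    (the RACIPE formalism), binarizes pooled stable steady states, and
    computes per-network resilience metrics (Sarle's bimodality
    coefficient, pairwise Spearman correlations, single-positive state
    fractions, bistable-to-monostable ratios, multiple linear regression
    coefficients) together with in-degree meta-analyses across network
    orders and mean connectivities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
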