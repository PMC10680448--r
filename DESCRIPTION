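Package: reefguest
Title: Structure and Species Importance in Sponge Host-Guest Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing binary bipartite host-guest interaction
    networks on tropical coral reefs. Builds a qualitative incidence matrix
    from species-level interaction records, quantifies network-level
    nestedness (NODF) and Barber bipartite modularity with simulated
    annealing, tests both against fill- and marginal-preserving null
    ensembles, computes seven complementary species-level structural
    descriptors (degree, betweenness, closeness, Katz centrality,
    among-module connectivity, within-module standardized degree, and
    per-species nestedness contribution), collapses them into a single
    importance index via principal coordinate ordination, derives the
    accumulated reef-cropped geographic area of each host from occurrence
    records, and relates importance to traits through a Poisson GLM,
    one-way ANOVAs, and a publication-bias meta-analysis of proportions.
    A seeded synthetic-data generator produces full input bundles with
    planted nested and modular structure for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    metafor,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
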