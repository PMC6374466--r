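Package: reefconnect
Title: Coral Meta-Population Genetics and Larval Dispersal Connectivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coupled analysis of coral meta-population structure along a
    western-boundary current: microsatellite population genetics (clone and
    multilocus-genotype detection, diversity and rarefied allelic richness,
    Weir-Cockerham FST, Jost's DEST, hierarchical AMOVA with permutation
    tests, exact differentiation tests with sequential Bonferroni
    correction, PCoA, Nei-distance neighbour-joining trees, Bayesian
    individual assignment) together with a biophysical larval-dispersal
    simulation (degree-day spawning phenology keyed to full moons,
    Lagrangian particle tracking with settlement rules, annual and
    multi-generation connectivity matrices) and isolation-by-distance
    Mantel tests against Euclidean, sea-path and connectivity-derived
    distances. A synthetic-data module generates genotypes with known
    differentiation, gridded current fields, sea-surface temperature series
    and lunar calendars so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
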