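Package: driftgrid
Title: Spatially Explicit Moran-Model Simulation of Genetic Drift on a
    Lattice
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates neutral genetic drift in a finite haploid
    population arranged on a bounded two-dimensional grid.  The engine is
    a death-birth Moran (voter-model) kernel with Moore (8-cell)
    neighbourhoods, infinite-alleles mutation, and Hoppe's-urn
    initialization; users can draw barriers and corridors that restrict
    gene flow, force mutations into chosen cells, record allele-count and
    allele-frequency trajectories, detect fixation globally and per
    connected component, and replay seeded runs bit-identically.  Four
    scripted experiments reproduce classic classroom demonstrations of
    drift, gene flow and mutation-drift balance.
License: MIT + file LICENSE
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
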