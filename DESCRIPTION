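Package: blastomere
Title: Multi-Level Statistical and Biomechanical Modelling of Cleavage-Stage
    Cell Lineages
Version: 0.1.0
Authors@R:
    person("BioModelling", "Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing digital cell-lineage trees of cleavage-stage
    embryos (sea-urchin blastula and similar systems). Reads and validates
    tab-separated lineage exports from cell-tracking workflows, extracts
    per-cell temporal and geometric features, aligns embryos of a cohort by
    affine temporal and linear spatial rescaling, fits normal and log-normal
    feature distributions per (generation, cell type) group, propagates them
    through a recursive multi-level probabilistic model, aggregates a cohort
    into a Kullback-Leibler centroid prototype, simulates stochastic
    artificial lineages, and embeds them in three-dimensional space with an
    overdamped particle model of the monolayered epithelium whose adhesion
    parameters are explored on a fitness landscape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
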