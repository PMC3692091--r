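Package: flexens
Title: Coarse-Grained Monte Carlo Simulation of Near-Native Protein Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates near-native dynamics of a globular protein from a single
    PDB structure using a coarse-grained (up to four interaction centers per
    residue) chain model sampled by Metropolis Monte Carlo over small local
    moves under near-native distance restraints. From the resulting Ca-trace
    trajectory it computes the per-residue mean-square-fluctuation profile,
    reduces the trajectory by K-means clustering to density-ranked medoid
    representatives, rebuilds backbone atoms (N, C, O, Cb) from each Ca trace,
    and superimposes the ensemble by iterative maximum-likelihood superposition
    with variance-based downweighting. Includes a fixed-column PDB reader and
    multi-model writer, a 3-state secondary-structure assigner based on
    backbone hydrogen-bond geometry, and generators for synthetic test
    structures and ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
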