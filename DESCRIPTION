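Package: pottsmaxent
Title: Maximum-Entropy Potts Models on Discrete-State Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers maximum-entropy (inverse Potts) models for systems of
    discrete-state nodes on arbitrary symmetric networks.  Constrains
    per-state densities and near-neighbour couple densities, trains the
    field vector h and coupling matrix J by chi-squared minimisation with
    Metropolis Monte Carlo sampling, importance-sampling reweighting and an
    effective-sample-size refresh criterion, and computes a variational
    entropy by thermodynamic integration along the recorded training path.
    Includes a dynamical extension for time sequences on a time-extended
    network, conditional (clamped) sampling for missing-state prediction,
    an image-discretisation front end, and built-in Hopfield, predator-prey
    lattice and exact-Potts fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
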