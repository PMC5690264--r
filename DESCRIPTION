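Package: bymweights
Title: Bayesian Small-Area Disease Mapping with Flexible ICAR Spatial Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for small-area ecological studies of health outcomes
    that ask how the specification of spatial structure - adjacency and
    pairwise spatial weights - affects Bayesian disease-mapping results.
    Extracts and audits queen-contiguity adjacency from polygon maps
    (exact and tolerance-based vertex matching, WinBUGS num/adj files),
    builds equal and variable product weights (population, density,
    expected count), performs indirect standardization, and fits the
    Poisson Besag-York-Mollie convolution model with an intrinsic
    conditional autoregressive (ICAR) prior under arbitrary symmetric
    weights by Metropolis-within-Gibbs MCMC. Includes DIC-based model
    comparison, exceedance probabilities, Gelman-Rubin and Monte Carlo
    error diagnostics, and a synthetic lattice-data generator with
    controlled vertex-coordinate discrepancies for validating adjacency
    extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
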