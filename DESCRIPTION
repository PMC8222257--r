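Package: pollinet
Title: Bayesian Reconstruction of Plant-Pollinator Networks from Visitation Counts
Version: 0.1.0
Authors@R:
    person("pollinet", "developers", email = "pollinet@example.org", role = c("aut", "cre"))
Description: Infers networks of preferred plant-pollinator interactions from
    noisy visitation count matrices. Observed visits are modelled as Poisson
    counts whose means combine sampling effort, relative species abundances
    and a multiplicative preference factor attached to the edges of a latent
    binary bipartite network. The latent network is marginalized analytically
    and the remaining parameters are sampled with Hamiltonian Monte Carlo,
    yielding posterior probabilities for every edge, posterior distributions
    of network metrics (connectance, NODF nestedness, degree distributions),
    and posterior-predictive model checks based on a chi-squared discrepancy.
    Includes generators for synthetic visitation data from the same model,
    parameter-recovery experiments, and readers for labelled CSV and
    Web of Life style interaction matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
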