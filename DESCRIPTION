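Package: imcoal
Title: Bayesian Isolation-with-Migration Inference from Multi-Locus Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the two-population isolation-with-migration (IM) coalescent
    model to multi-locus DNA sequence alignments by Markov chain Monte Carlo.
    Genealogies with migration events are sampled jointly with the six scaled
    demographic parameters (theta1, theta2, thetaA, m1, m2, t) under the
    structured coalescent, with per-locus sequence likelihoods computed either
    by Felsenstein pruning under the HKY85 substitution model or by mutation
    mapping under the infinite-sites model. Includes Metropolis-coupled chains,
    a matching coalescent simulator for HKY and infinite-sites data, posterior
    summaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
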