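Package: mdynemo
Title: Multi-Dynamic Network Modes for Time-Varying Power and Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers potentially uncoupled power and functional-connectivity (FC)
    dynamics from multichannel amplitude-envelope time series. The observation
    model factorises the instantaneous covariance into a diagonal standard-
    deviation part and a unit-diagonal correlation part, each generated as a
    time-varying convex mixture of learnable spatial modes whose mixing weights
    follow separate latent dynamics with a recurrent (LSTM) prior. Training
    minimises the variational free energy with an amortized bidirectional-LSTM
    posterior and the reparameterisation trick. Includes the single-dynamic
    special case, a hidden-Markov ground-truth simulator, the sliding-window /
    K-means baseline, and post-hoc statistics: mode matching, coupling tests,
    network recalculation under a fixed dynamic, and evoked-response GLMs with
    maximum-statistic permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    signal,
    jsonlite,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
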