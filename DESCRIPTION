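Package: pivae
Title: Prior-Encoding Variational Autoencoders as Stochastic-Process Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage Bayesian inference with prior-encoding variational
    autoencoders (piVAE). Stage one trains a variational autoencoder with a
    trainable kernel feature map on draws from a stochastic-process prior
    (Gaussian processes, monotone cubic families, log-Gaussian Cox processes),
    learning a low-dimensional latent basis expansion of the function class.
    Stage two uses the frozen decoder and feature map as a drop-in
    stochastic-process prior: posterior inference over the latent variables is
    carried out by a built-in No-U-Turn Hamiltonian Monte Carlo sampler, with
    split rank-normalised R-hat and effective-sample-size diagnostics,
    posterior predictive summaries, and seeded benchmark experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
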