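Package: epactive
Title: Bayesian Active Learning of Spatially Varying Cardiac Tissue Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast posterior estimation of spatially varying tissue excitability
    in a phenomenological cardiac electrophysiology model. A two-variable
    Aliev-Panfilov reaction-diffusion model is solved on a graph-Laplacian
    discretization of a cardiac node cloud and mapped to multi-lead ECG through
    a linear lead field. A variational autoencoder embeds high-dimensional
    excitability fields into a two-dimensional latent space, and a Gaussian
    process surrogate of the latent log-posterior is trained by Bayesian active
    learning with acquisition functions derived from the log-normal process
    exp(GP). Direct and delayed-acceptance (two-stage) Metropolis-Hastings
    samplers provide reference posteriors, and kernel density summaries with
    Dice, RMSE and correlation metrics evaluate the recovered excitability
    fields.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
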