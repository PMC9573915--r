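Package: icarlap
Title: Maximum Likelihood Estimation of Intrinsic CAR Poisson Models by
    Laplace Approximation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits Besag intrinsic conditional autoregressive (ICAR)
    Poisson models for small-area disease counts by maximum likelihood,
    integrating the latent spatial field out of the joint likelihood with
    a Laplace approximation.  Includes first-order contiguity graph
    construction from ESRI shapefiles or edge lists, a spectral simulator
    for ICAR fields and Poisson counts, brute-force quadrature oracles
    for validating the Laplace machinery on tiny graphs, a
    Metropolis-within-Gibbs cross-check sampler, and a command-line
    interface for fitting, simulating and validating.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
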