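Package: phagedyn
Title: Phage-Bacteria Population Dynamics with Distributed Latent Periods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulators for bacteriophage-bacteria predator-prey dynamics that
    account for cell-to-cell heterogeneity in the latent period. Implements the
    classic fixed-delay differential equation (DDE) model, the distributed-delay
    (DDDE) model in which lysis is a convolution over a latent-period density
    (truncated normal, lognormal, gamma or point mass), and the transit-compartment
    (TC) approximation obtained from the linear chain trick. Includes a
    latent-period-dependent burst-size law with population-mean normalisation, a
    synchronized-infection single-step growth assay and first-lysis (infective
    center doubling) time, a normalised area-between-curves error metric, and a
    Monte Carlo framework that quantifies the prediction error of fixed-delay and
    transit-compartment approximations over randomized kinetic parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
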