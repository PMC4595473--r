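Package: ip3rgating
Title: Modal Gating Analysis of IP3 Receptor Channels and Local Calcium
    Release Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Twelve-state aggregated Markov model of inositol
    1,4,5-trisphosphate receptor (IP3R) single-channel gating in the
    presence of wild-type and familial Alzheimer's disease mutant
    (M146L) presenilin-1.  Provides equilibrium observables (open
    probability, modal prevalences, mean open/closed times, modal
    lifetimes), closed-form dwell-time distributions via sub-generator
    matrix exponentials, maximum-likelihood fitting of flux parameters
    to idealized dwell sequences, a synthetic gating-record generator
    with burst filtering and modal segmentation, and a hybrid
    stochastic reaction-diffusion simulation of calcium puffs and
    blips at a ten-channel release site.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
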