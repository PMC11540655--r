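Package: brachysim
Title: Meshless Biomechanical Simulation of Needle Insertion in Prostate
    Brachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator of prostate deformation during high-dose-rate
    brachytherapy needle insertion. Implements a meshless total-Lagrangian
    explicit-dynamics solver with interpolating modified moving least squares
    shape functions and a near-incompressible Neo-Hookean constitutive model,
    a kinematic tip-following rule for sequential anchor-needle and
    catheter-needle insertion with regional stiffening, a synthetic prostate
    phantom generator, binary-mask import, and evaluation via Dice similarity
    on a common cubic voxel domain together with in-plane displacement
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
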