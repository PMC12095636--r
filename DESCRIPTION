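Package: boostsit
Title: Spatial Efficacy Analysis of Sterile Insect Technique Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for area-wide mosquito suppression trials using
    the (boosted) sterile insect technique. Standardizes trap-level egg and
    adult counts from paired treated/control sites into relative densities,
    builds the spatial support of the trap network (Voronoi cells, contiguity
    graph, scaled intrinsic conditional autoregressive precision), fits a
    Bayesian spatial Poisson model of suppression with a BYM2 random effect
    using a built-in Markov chain Monte Carlo sampler, maps posterior success
    probabilities against a suppression threshold, compares treatment regimes
    with a trap-by-month block permutation test, and summarizes release
    campaigns (release density, sterile-to-wild ratios, recapture fractions).
    Includes a synthetic-trial generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
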