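Package: plaquedyn
Title: Dynamic Models of Atherosclerotic Plaque Progression and Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time models of atherosclerotic plaque dynamics.
    Implements a logistic-map model of plaque burden with a dynamic
    aggregate growth rate, positive lumen remodeling, regime and chaos
    analysis (Lyapunov exponents, period-doubling onset), instability
    proportions as a function of stenotic degree, and growth-rate
    estimation from serial planimetric measurements. A ladder of Markov
    models for plaque stability is provided alongside: a two-state
    stable/unstable chain with covariate-weighted transition
    probabilities and stationary-distribution analysis, a spatial
    extension over a lattice of plaque-surface sites with a dependence
    matrix and instability heatmaps, and a Markov random field with
    site and pair potentials, exact enumeration on small lattices and
    Gibbs sampling. Seeded synthetic-data generators supply surveillance
    series and covariate fields for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
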