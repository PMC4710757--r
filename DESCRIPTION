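Package: clampfitr
Title: Hybrid Particle-Swarm and Trust-Region Estimation of Cardiac
    Ion-Current Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates Hodgkin-Huxley-type potassium current formulations
    (the rapid, ultra-rapid, and slow delayed rectifiers of the Courtemanche
    human atrial myocyte model) against step voltage-clamp recordings.
    Currents are simulated piecewise-analytically under multi-sweep step
    protocols, and parameters are estimated by bounded trust-region-reflective
    nonlinear least squares, constriction-coefficient particle swarm
    optimization with boundary re-randomization, their sequential two-stage
    combination, or a per-iteration hybrid that embeds capped trust-region
    refinement into every swarm iteration. Includes a synthetic-data generator
    with calibrated additive Gaussian noise, experiment drivers for repeated
    seeded runs and noise-sensitivity studies, and plain-text trace input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
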