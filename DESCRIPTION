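Package: growthnoise
Title: Noise Propagation Between Stochastic Gene Expression and Cell Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for an integrated stochastic model of bacterial gene
    expression, metabolism and growth in which every protein is synthesized
    with Ornstein-Uhlenbeck noise, jointly limits the instantaneous growth
    rate, and is diluted by growth. Provides stochastic trajectory
    simulation of proteome mass fractions and growth rate; growth-control
    coefficient (GCC) analysis with the intensive zero-sum and flux-control
    sum rules; closed-form linear-noise statistics including stationary
    coefficients of variation, dual-reporter covariances, and
    expression-growth cross-correlations decomposed into control, autogenic,
    dilution and transmission noise modes; and a builder for a
    many-protein (1021 species) cell model with a lac-operon reporter
    construct on a Monod growth curve and a synthetic proteome emulating
    measured abundance/noise spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
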