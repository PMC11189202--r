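Package: bsabkin
Title: Mechanistic Mass-Action Modeling of Bispecific Antibody-Receptor
    Binding Kinetics
Version: 0.1.0
Authors@R:
    person("bsabkin", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits the cell-surface binding kinetics of
    homobivalent (tocilizumab, 10H2) and heterobivalent bispecific (BS1)
    antibodies against the interleukin-6 and interleukin-8 receptors using
    mass-action ordinary differential equations. Includes a
    thermodynamic-cycle-constrained rate-constant parameterization, a stiff
    Rosenbrock integrator, flow-cytometry style dose-response assay
    simulation with washout, multi-start bounded nonlinear least-squares
    parameter estimation with Latin hypercube initial guesses and four
    normalization schemes, binary/ternary complex occupancy analyses,
    a synthetic dose-response data generator, and local/global univariate
    sensitivity analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
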