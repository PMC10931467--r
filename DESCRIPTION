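Package: smadsim
Title: Compartmental Dynamics of Social Media Addiction and Depression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulator and analysis toolkit for a six-compartment
    (susceptible, exposed, addicted, depressed, recovered, quitter)
    ordinary-differential-equation model of social media addiction and the
    depression it induces. Provides the vector field and analytic Jacobian,
    the basic reproduction number in closed form and via the
    next-generation matrix, disease-free and endemic equilibria,
    eigenvalue-based local stability diagnostics, center-manifold forward
    bifurcation coefficients, normalized forward sensitivity indices,
    Latin-hypercube/PRCC global sensitivity analysis, and a fixed-step
    fourth-order Runge-Kutta integrator with scenario management.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
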