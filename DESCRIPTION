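Package: cytotriad
Title: Dynamics, Stability and Sensitivity of a Three-Cytokine
    Post-Stroke Inflammation Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a nonlinear ordinary differential
    equation model of the TNF-alpha / IL-6 / IL-10 cytokine network in
    acute post-stroke inflammation.  The model couples mutual
    pro-inflammatory amplification between TNF-alpha and IL-6 with
    delayed, Hill-gated induction of the anti-inflammatory mediator
    IL-10 and its multiplicative suppression of both pro-inflammatory
    species.  Provides a breakpoint-aligned fixed-step fourth-order
    Runge-Kutta integrator with intervention schedules (boluses,
    parameter modulations) and therapeutic scenario presets;
    exhaustive steady-state enumeration by scalar reduction with
    Jacobian assembly, eigenvalue stability classification and the
    closed-form pre-delay linear solution; saddle-node (fold)
    detection, hysteresis sweeps and branch regression over parameter
    grids; and variance-based global sensitivity analysis (Latin
    hypercube / Saltelli sampling with Sobol first- and total-order
    indices).  All results are returned as tibbles with ggplot2
    autoplot(), tidy() and glance() methods, and a small command-line
    interface is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
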