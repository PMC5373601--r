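Package: ktzlog
Title: Dynamics and Bifurcation Analysis of the Logistic KT/KTz Map-Based
    Excitable Cell Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the KTLog and KTzLog
    map-based excitable-cell models, a discrete-time neuron/cardiac-cell
    family with a logistic gain function f(u) = u/(1+|u|).  Provides the
    exact one-step map and fast compiled trajectory simulation, closed-form
    fixed points and eigenvalues with stability classification, analytic
    stability-limit curves and Arnold-tongue winding numbers, interspike
    interval (ISI) based regime classification and phase diagrams, Lyapunov
    exponent estimators (twin-trajectory divergence and Eckmann-Ruelle
    tangent-space methods), capacity and Kaplan-Yorke attractor dimensions,
    bifurcation location and power-law scaling fits near infinite-period
    and blue-sky transitions, a gallery of excitable-behavior protocols,
    and gap-junction coupled networks (chains and complete graphs).
    Includes a command-line interface for batch runs and reproduction of
    the model's standard diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
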