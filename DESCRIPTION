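Package: aneuflow
Title: Idealized Aneurysm Hemodynamics, Wall Shear Stress Metrics, and
    Rupture-Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics for sidewall intracranial
    aneurysms. Builds parametric two-dimensional aneurysm geometries,
    discretizes them on a staggered Cartesian grid, solves unsteady
    incompressible Newtonian flow with pulsatile inflow by a finite-volume
    SIMPLE method, and post-processes wall shear stress (WSS) into the
    standard rupture-risk metric suite: cycle-averaged WSS, mean and highest
    sac WSS (MWSS, HWSS), parent-vessel reference WSS (PWSS), low shear area
    ratio (LSAR), and aneurysm-to-parent WSS ratios. A synthetic cohort
    generator emulates a ruptured/unruptured study population stratified by
    neck morphology, and a statistics pipeline applies normality-gated group
    tests, Spearman correlations, univariate screening and backward stepwise
    logistic regression to produce group-comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    nortest,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
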