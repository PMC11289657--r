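Package: lsdsm
Title: Linear State Space Dynamic Survival Modelling of Longitudinal and
    Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint modelling of longitudinal biomarker trajectories and
    time-to-event outcomes with the linear state space dynamic survival
    model.  A canonical autoregressive linear-Gaussian state space model
    tracks the true (noise-free) biomarker values while a proportional
    hazards model driven by the hidden states governs survival.  Maximum
    likelihood estimation uses an expectation-maximization algorithm with
    survival-corrected Kalman filtering and Rauch-Tung-Striebel smoothing,
    Laplace/Newton-Raphson Gaussian approximations of the survival-corrected
    state posteriors, closed-form state-space parameter updates and a
    Newton-Raphson update for the hazard coefficients.  Includes
    individualized dynamic survival prediction from a landmark to a horizon,
    a cohort simulator with piecewise-exponential event times, and
    landmark/horizon evaluation metrics (inverse-probability-of-censoring
    weighted dynamic AUC and time-dependent Brier score, trajectory and
    survival-curve RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
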