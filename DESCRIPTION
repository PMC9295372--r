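Package: pkswarm
Title: Pharmacokinetic Analysis with Swarm-Initialized Neural Network
    Concentration Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-dose pharmacokinetic studies of delayed-release
    oral formulations: a calibrated synthetic cohort simulator (one-compartment
    first-order absorption with lag time and covariate effects on clearance and
    volume), noncompartmental parameter estimation (Cmax, Tmax, AUC, terminal
    slope), age/gender group comparisons, principal-component reduction of
    demographic and laboratory covariates, a feedforward neural network trained
    by Levenberg-Marquardt with early stopping whose initial weights can be
    supplied by particle swarm, whale, or genetic global optimizers, and
    mean-impact-value covariate importance for the fitted
    covariates-to-concentration prediction function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
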