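Package: meroeval
Title: External Evaluation and Bayesian Forecasting of Meropenem Population Pharmacokinetic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the external evaluation of published population
    pharmacokinetic models of meropenem in critically ill patients, including
    patients on continuous renal replacement therapy. Provides a declarative
    registry of 14 published model definitions, closed-form one- and
    two-compartment infusion kinetics under arbitrary dosing histories,
    maximum a posteriori (MAP) Bayesian estimation of individual random
    effects from therapeutic drug monitoring observations,
    prediction-based diagnostics (MDPE, MAPE, F20, F30, relative bias and
    RMSE), simulation-based diagnostics (prediction-corrected visual
    predictive checks and normalized prediction distribution errors),
    dose-adaptation classification against the 8-45 mg/L target window, and a
    seeded synthetic ICU cohort generator emulating routine meropenem TDM
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
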