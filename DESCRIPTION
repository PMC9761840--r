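Package: lethaltime
Title: Time-Based Prediction of Chemical Mixture Toxicity in Aquatic Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the lethal effect of chemical mixtures on
    aquatic organisms from single-chemical acute-toxicity data. Estimates
    median lethal concentrations (LC50) and times (LT50) from quantal
    bioassay data by maximum-likelihood probit analysis with Fieller
    fiducial limits, fits the log-log lethal-time law ln(LT50) = a + b ln(C),
    combines component lethal times into a mixture LT50 by lethal-time
    addition, predicts time-resolved mortality with the hyperbolic
    (Michaelis-Menten shaped) model, computes the concentration-addition
    reference prediction, and scores predicted against observed mixture
    LC50s with the model deviation ratio (MDR). Includes a seeded
    time-to-death bioassay simulator and a bundled acute-toxicity case
    study of four pesticides in African catfish (Clarias gariepinus) and
    Nile tilapia (Oreochromis niloticus).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
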