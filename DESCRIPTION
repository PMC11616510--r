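Package: mdtreat
Title: Reactive-Transport Modelling and Calibration for Passive Mine-Drainage Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pilot-scale passive treatment of manganese- and
    zinc-rich mine drainage in a limestone bioreactor. Implements a 1D advective
    (optionally dispersive) cells-in-series reactive-transport model with biotic
    pseudo-first-order Mn(II) oxidation and linear-driving-force Zn(II) sorption
    on a growing birnessite inventory; inverse estimation of the kinetic
    parameters (oxidation rate constant, mass-transfer coefficient, distribution
    coefficient) from inlet/outlet monitoring series by Levenberg-Marquardt
    weighted least squares; an error-metric suite (MAE, RMSE, NRMSE,
    Nash-Sutcliffe R squared); hydraulic-retention-time optimisation against
    effluent limits; a synthetic monitoring-campaign generator with known ground
    truth; and linear-combination fitting of normalised XANES spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
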