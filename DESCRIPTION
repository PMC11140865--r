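Package: pplferkit
Title: Thermodynamically Consistent Physical-Chemical Property Prediction
    with PPLFER Equations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts partition ratios (octanol-water wet and dry,
    octanol-air, air-water), vapor pressure and solubilities in water and
    octanol for neutral organic solutes from Abraham solute descriptors
    using poly-parameter linear free energy relationship (PPLFER)
    equations. System parameters for the nine endpoints are kept
    thermodynamically consistent through three-solubility property cycles
    with propagation of standard errors. Includes applicability-domain
    diagnostics (leverage, chemical similarity score, negative-domain
    check) summarised as ordinal uncertainty levels, root mean squared
    error of prediction (RMSEP) aggregation for meta-models, calibrated
    95 percent prediction intervals, Van't Hoff solid to supercooled
    liquid conversion, boundary capping of solubility and vapor pressure,
    multiple linear regression calibration of system parameters, and a
    validation-statistics engine with uncertainty-level stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
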