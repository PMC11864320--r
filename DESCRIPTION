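Package: firecarb
Title: Climate-Sensitive Wildfire Risk, Tree Mortality and Forest Carbon
    Emission Modelling
Version: 0.1.0
Authors@R:
    person("firecarb", "maintainers", email = "firecarb@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling annual wildfire occurrence probability and
    fire-related tree mortality on forest inventory plots from seasonal
    climate covariates, and for converting the resulting burn probabilities
    into forest CO2 emission estimates under combustion scenarios. Derives
    fire-season and spring climate covariates (precipitation, maximum
    temperature, and modified-Hargreaves potential evapotranspiration) from
    monthly climate normals; builds inverse-squared-distance spatial weights
    with a distance cutoff and computes Moran's I with permutation inference;
    fits spatial autoregressive (SAR) regressions by profiled least squares
    with backward elimination of interaction terms; ships transcribed
    published coefficient tables for plug-in prediction; and accounts for
    burned area, combusted biomass, and CO2 emissions over a scenario grid
    of combustion conversion rates. A synthetic-landscape generator built on
    Gaussian random fields and a Gaussian copula emulates the statistical
    structure of national forest-inventory plot data so that the whole
    pipeline is testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
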