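Package: soilcoupling
Title: Data-Driven Analysis of Soil Moisture-Temperature Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the coupling between hourly soil
    temperature and volumetric soil moisture series measured at depth in a
    cropped soil profile. The pipeline removes the diurnal cycle by 24-hour
    seasonal differencing, screens each series with augmented Dickey-Fuller
    unit-root tests (no-constant, drift, and trend variants with MacKinnon
    response-surface critical values and p-values), fits bivariate vector
    autoregressions by conditional Gaussian maximum likelihood with
    AIC/BIC lag-order selection and companion-matrix stability checks,
    derives unit-shock impulse-response functions (reduced-form, Cholesky,
    or generalized identification) with residual-bootstrap confidence
    bands and the response time-lag and intensity summaries used to grade
    coupling strength, and runs bivariate Granger causality F-tests.
    A seeded generator of coupled synthetic series with known ground truth
    supports end-to-end validation, and broom-style tidy() and glance()
    methods plus ggplot2 autoplot() methods cover every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
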