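Package: rbale
Title: Simulation and Estimation for Long-Term Repetitive-Batch Adaptive
    Laboratory Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing long-term repetitive-batch
    adaptive laboratory evolution (rbALE) experiments run in microbioreactor
    plates with well recycling. Provides a discrete-event simulator of the
    threshold-triggered transfer workflow (measurement cycles, tempering,
    harvest, inoculation, washing and drying constraints, wrap-around well
    reuse, fan-out layouts), the underlying bioprocess models
    (piecewise-exponential growth with transfer-event dilution, linear
    backscatter calibration, wild-type/mutant competition, Monod batch
    kinetics), a seeded synthetic-data generator for backscatter and
    bioreactor time series, and estimation stages that recover per-batch
    growth rates, dilution factors and yields by nonlinear least squares
    with residual-bootstrap uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
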