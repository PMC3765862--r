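Package: physupply
Title: Physician Supply Forecasting with Stock-and-Flow Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time system-dynamics simulation of a national physician
    workforce: a stock-and-flow engine with conveyor-style delay chains, a
    wired model of the Japanese physician career path (medical school,
    national examination, postgraduate clinical training, speciality choice,
    clinical practice, retirement), a supply-versus-need sufficiency criterion
    with a speciality-maldistribution flag, backcast validation against
    historic census series (relative error and mean-squared-error summaries),
    quota and speciality-choice scenario sensitivity analysis, and synthetic
    generators for every input (workforce census, enrolment quota series,
    required-number survey, population projection) together with a calibration
    routine for the constant retirement hazard.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
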