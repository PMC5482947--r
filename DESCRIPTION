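Package: sivar
Title: Model-Based Insulin Sensitivity and Its Hour-to-Hour Variability in Critical Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based analysis of glycaemic control in intensive care.
    Implements a three-compartment glucose-insulin kinetic model (ICING family) with
    forward simulation under piecewise-constant insulin and nutrition inputs, hourly
    identification of insulin sensitivity (SI) by the integral method, the forward
    hour-to-hour percentage change in SI as a variability statistic, bootstrap
    difference-of-medians and Kolmogorov-Smirnov testing in 6-hour blocks, clinical
    equivalence testing against a blood-glucose measurement-error derived range, and a
    virtual-patient cohort generator with a stylised insulin-nutrition feedback protocol
    for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
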