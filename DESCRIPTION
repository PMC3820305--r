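Package: ibfstem
Title: Iterative Bayesian Framework for Stem Cell Differentiation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning and analysing stem cell differentiation time
    courses with an iterative Bayesian framework (IBF). Provides a seven-marker
    germ-layer classifier for flow-cytometry-style event tables, a synthetic
    embryoid-body population simulator, logistic and Gaussian-rate fits of
    differentiation kinetics, beta-binomial predictive monitoring with
    sequential stopping rules and prior-sensitivity analysis, a two-iteration
    adaptive sampling-window designer that narrows from 24-hour to 12-hour
    resolution, competing-risks survival analysis of commitment times, and a
    likelihood-ratio calculator for the probability of malignancy of solitary
    pulmonary nodules.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    minpack.lm,
    survival,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
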