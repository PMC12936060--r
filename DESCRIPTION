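Package: tempmort
Title: Distributed Lag Non-Linear Modelling of Temperature-Attributable Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-series analysis of daily temperature and mortality:
    natural cubic spline cross-bases over exposure and lag, quasi-Poisson
    regression with seasonal/long-term trend and day-of-week control, overall
    cumulative and lag-specific exposure-response curves, minimum mortality
    temperature (MMT) estimation with approximate parametric bootstrap
    intervals, and decomposition of temperature-attributable mortality into
    extreme/moderate cold and heat components with Monte-Carlo empirical
    confidence intervals. Includes a synthetic daily-series generator with a
    known exposure-lag-response surface for parameter-recovery and calibration
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
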