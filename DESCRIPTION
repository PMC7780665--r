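Package: longlag
Title: Long-Term Exposure Effects from Case-Only Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of long-term (months to years) environmental exposure
    effects on daily event counts using constrained distributed-lag Poisson
    regression with overdispersion. Provides alternative adjustment bases for
    seasonality and long-term time-trend (natural cubic splines of running
    time, or combinations of day-of-year splines, year indicators and
    week/month-order splines), overfitting diagnostics based on residual
    exposure variance, a synthetic daily time-series generator with mortality
    displacement, a Monte-Carlo harness reporting bias, sampling variability
    and confidence-interval coverage, seasonality-deviation dummy sensitivity
    analyses, and two-stage multivariate random-effects pooling of
    city-specific lag coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
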