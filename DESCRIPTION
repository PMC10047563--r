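Package: lagcast
Title: Hindcast-Augmented Probabilistic Forecasting of Monthly Surveillance Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step hindcast-then-forecast modelling of monthly
    jurisdiction-level mortality surveillance series under realistic
    reporting delays. Official mortality data released in annual batches
    lag one to two years behind real time; lagcast first estimates the
    unobserved gap months (hindcasts) from the mortality history and
    near-real-time proxy streams (crisis-hotline call rates, search-engine
    query rates), then appends those estimates to the observed series and
    issues six-month-ahead probabilistic forecasts as 23-level quantile
    sets. Includes a correlated synthetic panel generator (Gaussian
    copula over trend/seasonal marginals), a data-release calendar and
    masking layer enforcing real-time discipline, random-walk-with-drift
    and dynamic harmonic regression models with ARIMA errors and
    exogenous proxies, rolling-origin backtesting, quantile/pinball
    scoring with relative skill and Wilcoxon comparisons, calibration
    curves with a Cramer-type distance, and Vincentized multi-model
    ensembles (exponential smoothing, order-searching ARIMA, neural
    autoregression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
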