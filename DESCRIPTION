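Package: longcov
Title: Residual Covariance Structure Selection for Longitudinal Marginal Models
Version: 0.1.0
Authors@R:
    person("Longcov", "Developers", email = "longcov@example.org", role = c("aut", "cre"))
Description: Tools for choosing the residual covariance structure of marginal
    linear models for longitudinal data. Simulates balanced repeated-measures
    datasets with known residual correlation (compound symmetry, autoregressive,
    and continuous-time spatial families) via Yule-Walker correlation algebra,
    diagnoses the residual correlation of a naive fixed-effects fit through
    lag-mean profiles and a pooled partial autocorrelation function, fits
    marginal linear models with structured residual covariance by maximum or
    restricted maximum likelihood with optional heteroscedastic per-occasion
    variances, and compares candidate structures with AIC, BIC and AICc.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
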