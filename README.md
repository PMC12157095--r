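# longcov

Residual covariance structure selection for longitudinal marginal linear
models.

## Who this is for

Analysts of longitudinal (repeated-measures) data — one outcome measured on
each subject at several occasions — who need to decide how to model the
within-subject residual correlation before trusting the standard errors of
a linear model. Ignoring that correlation underestimates uncertainty;
picking a structure by trial and error invites overfitting. `longcov`
automates a principled route: *diagnose* the correlation left in the
residuals of a fixed-effects-only fit using time-series tools, then
*confirm* the suggested structure by likelihood-based comparison.

## The model and the method

The marginal model per subject $i$ is

$$ y_i = X_i\beta + \varepsilon_i, \qquad
   \varepsilon_i \sim N\!\left(0,\ \sigma^2 D^{1/2} R(\theta) D^{1/2}\right) $$

with $R(\theta)$ a $T\times T$ correlation matrix — compound symmetry (CS),
discrete AR($p$) built from the Yule-Walker equations
$\rho_k=\sum_{i=1}^{p}\phi_i\rho_{k-i}$, continuous-time kinds (continuous
AR(1), exponential, Gaussian, linear, spherical, rational quadratic),
unstructured, or independence — and $D=\mathrm{diag}(\delta_t^2)$ optional
per-occasion variance weights ($\delta_1\equiv 1$). The workflow:

1. **Naive fit** (`fit_naive`): OLS on the mean structure, correlation
   deliberately ignored; residuals reshaped subjects × occasions.
2. **Diagnostics** (`lag_profile`, `pooled_pacf`, `suggest_structure`):
   the lag-mean profile of the residual correlation matrix (flat ⇒ CS,
   geometric decay ⇒ AR(1)) and a pooled partial autocorrelation function
   whose cutoff lag estimates the AR order.
3. **Structured fits** (`fit_marginal_model`): profiled ML/REML — $\beta$
   and $\sigma^2$ eliminated analytically, $\theta$ optimized through
   boundary-safe reparameterizations. Log-likelihoods match `nlme::gls`
   exactly (asserted in the test suite).
4. **Selection** (`compare_structures`, `run_pipeline`): AIC / BIC / AICc
   table, headline winner by BIC, agreement with the diagnostics reported.

A seeded simulator (`simulate_dataset`) generates balanced datasets with
known residual correlation for validation, and everything is reachable from
a CLI (`inst/cli/longcov`) with `simulate`, `diagnose`, `fit`, `compare`
and `run` subcommands.

## Worked example

```r
library(longcov)
d <- simulate_dataset(simulation_design(n_subjects = 100, times = 1:6,
  structure = corr_structure("AR", 0.5), seed = 42))
pooled_pacf(fit_naive(d, ~ time + group + age))
#> Pooled residual PACF (band = 0.08, suggested order = 1)
#>  lag    pacf significant
#>    1  0.4330        TRUE
#>    2  0.0510       FALSE
#>    3 -0.0192       FALSE
#>    4  0.0478       FALSE
#>    5 -0.0953        TRUE
```

The lag-1 spike (0.43, near the generating $\phi = 0.5$) followed by values
inside the band marks a first-order autoregression; the late isolated spike
at lag 5 is not part of the initial significant run and is correctly not
read as "order 5".

```r
run_pipeline(d, ~ time + group + age)
#> Analysis report
#> ===============
#> Dataset: 100 subjects x 6 occasions
#>
#> Suggested residual correlation structure: AR(1)
#>   PACF suggested order: 1 (band 0.08 )
#>   lag-profile flatness: 0.275 (tolerance 0.05 )
#>
#> Model fit comparison (sorted by BIC)
#>     structure  k  loglik     aic     bic    aicc converged best_aic best_bic best_aicc
#>         AR(1)  6 -775.87 1563.73 1590.08 1563.88      TRUE     TRUE     TRUE      TRUE
#>         AR(2)  7 -775.34 1564.68 1595.42 1564.87      TRUE    FALSE    FALSE     FALSE
#>            CS  6 -801.08 1614.16 1640.50 1614.31      TRUE    FALSE    FALSE     FALSE
#>  UNSTRUCTURED 20 -768.92 1577.84 1665.65 1579.30      TRUE    FALSE    FALSE     FALSE
#>
#> Selected by BIC: AR(1) (agrees with the residual diagnostics)
```

Every criterion picks AR(1), the generating structure: the unstructured fit
buys 7 log-likelihood points with 14 extra parameters and BIC rejects the
trade. `write_report(report, "report.json", "json")` serializes the whole
analysis (also `"csv-bundle"` and `"markdown"`); reports are byte-identical
across reruns on the same input.

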