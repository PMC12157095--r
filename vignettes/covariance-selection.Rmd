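---
title: "Selecting residual covariance structures for longitudinal marginal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting residual covariance structures for longitudinal marginal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longcov)
```

## The problem

Repeated measurements on the same subject are correlated. A linear model for
longitudinal data that specifies only fixed effects leaves that correlation
in its residuals, and inference that ignores it (underestimated standard
errors, inflated type I error) is unreliable. The marginal formulation
models the within-subject covariance directly:

$$ y_i = X_i \beta + \varepsilon_i, \qquad
   \varepsilon_i \sim N\!\left(0,\; \sigma^2\, D^{1/2} R(\theta)\, D^{1/2}\right), $$

where $R(\theta)$ is a $T \times T$ correlation matrix from a parametric
family, and $D = \mathrm{diag}(\delta_t^2)$ holds optional per-occasion
variance weights ($\delta_1 \equiv 1$). The practical question this package
addresses is *which family* — independence, compound symmetry (CS, one
common correlation $\rho$), a discrete autoregressive process AR($p$), a
continuous-time kind (continuous AR(1), exponential, Gaussian, linear,
spherical, rational quadratic), or a fully unstructured correlation — and
it answers it by combining time-series diagnostics with information-criterion
comparison rather than trial and error.

## Autoregressive correlation via the Yule-Walker equations

An AR($p$) process
$X_t = \phi_1 X_{t-1} + \dots + \phi_p X_{t-p} + \varepsilon_t$ ties its
autocorrelations $\rho_k$ to the coefficients through the Yule-Walker
equations $\rho_k = \sum_{i=1}^p \phi_i \rho_{k-i}$. `yw_autocorrelations()`
solves the exact $p \times p$ linear system for lags $k \le p$ and extends
by the recursion beyond — solving the system rather than recursing from
guessed initial values is what keeps higher lags consistent with the
process. `yw_coefficients()` inverts the matrix form $R\Phi = \Gamma$;
`theoretical_pacf()` runs Durbin-Levinson on the autocorrelations, and the
resulting partial autocorrelation function (PACF) cuts off exactly after
lag $p$, which is what makes the PACF an order detector. Stationarity is
enforced throughout by requiring every characteristic root to satisfy
$|z| > 1 + 10^{-8}$; the small margin rejects boundary parameters that
make the Yule-Walker system ill-conditioned.

```{r yw}
proc <- ar_process(c(0.5, 0.3))
yw_autocorrelations(proc, 4)
theoretical_pacf(proc, 4)
```

## The diagnostic stage

`fit_naive()` fits the mean structure by ordinary least squares —
generalized least squares with identity weights, i.e. deliberately ignoring
the correlation — and reshapes residuals into a subjects-by-occasions
matrix. Two summaries characterize what the model missed:

* `lag_profile()`: the mean of each off-diagonal of the residual
  correlation matrix against lag. A flat profile at $\rho$ indicates CS; a
  geometric decay indicates AR(1); the Yule-Walker pattern appears for
  higher orders.
* `pooled_pacf()`: lag-$k$ cross-products pooled over all subjects,
  demeaned by the pooled residual mean, divided by the number of products
  actually summed, $n(T-k)$, then passed through Durbin-Levinson. The
  significance band is the white-noise bound $1.96/\sqrt{nT}$.

`suggest_structure()` turns these into a candidate: no significant lag
$\to$ independence; one significant lag with a flat profile (maximum
absolute deviation from its mean below 0.05, configurable) $\to$ CS; one
significant lag with decay $\to$ AR(1); a run of $p$ significant lags
$\to$ AR($p$).

### Numerical choices worth knowing

*Pooled-ACF denominator.* Pooling with a denominator fixed at $nT$ for all
lags guarantees a positive-semidefinite autocovariance sequence, but it
shrinks lag $k$ by $(T-k)/T$ *regardless of the number of subjects* — at
$T = 10$ the expected lag-3 PACF of an AR(2) is then $-0.029$, comparable
to the significance band at realistic sizes, and order detection stays
distorted even as $n \to \infty$. We therefore divide by the count of
summed products $n(T-k)$, which is consistent at fixed $T$; positive
semidefiniteness can in principle fail, so the Durbin-Levinson step clamps
any partial correlation that leaves $[-1, 1]$ (never observed at the
suite's sizes).

*Order rule.* The suggested order is the length of the *initial
consecutive run* of significant PACF lags, not the largest significant lag
anywhere: an AR($p$) shows spikes up to lag $p$ after which values drop to
zero, and reading an isolated spurious spike at lag 7 as "order 7" would
make the detector's family-wise error grow with the number of lags
inspected.

*Band.* $1.96/\sqrt{nT}$ treats every subject as contributing $T$ points
to the pooled estimator. It is a pointwise, approximate null bound; the
suite measures the realized family-wise false-positive rate by simulation
(≤ 15 % across 9 lags at $n = 500$).

*Ties.* A PACF value exactly on the band is non-significant.

## Fitting: profiled (RE)ML

`fit_marginal_model()` maximizes the Gaussian likelihood with $\beta$ and
$\sigma^2$ profiled out analytically: at each $\theta$, $\hat\beta(\theta)$
is the GLS solution and $\hat\sigma^2(\theta) = \mathrm{RSS}/N$ (ML) or
$\mathrm{RSS}/(N-p)$ (REML); the REML objective carries the extra
$\log|\sum_i X_i' W_i^{-1} X_i|$ term and matches the `nlme::gls`
log-likelihood convention exactly (the test suite asserts equality against
`gls` fits). For balanced data the per-iteration cost is independent of the
number of subjects: subject sums enter only through precomputed
cross-occasion moment matrices contracted with $W^{-1}$.

The bounded $\theta$ domain is handled by optimizing in an unconstrained
reparameterization: AR coefficients through their partial autocorrelations
mapped by $\tanh$ (stationary for every unconstrained point), CS $\rho$
through a scaled logistic onto $(-1/(T-1),\, 1)$, continuous-time ranges
through $\log$, variance weights through $\log$, and the unstructured
correlation through the spherical angles of its unit-row Cholesky factor.
BFGS runs from three fixed deterministic starts (null correlation, moderate
positive, and a start informed by the naive residual correlation), best
objective wins, ties broken by smaller parameter norm — except the
unstructured family, which uses the profile-informed start alone: with
$T(T-1)/2$ parameters the objective is effectively unimodal around the
sample residual correlation and the generic starts only triple the cost.
Convergence uses a relative objective tolerance of $10^{-8}$ with at most
500 iterations; non-convergence sets a flag on the result, never an
exception, and a non-positive-definite covariance during search yields a
large finite penalty rather than `NaN`.

Degenerate designs are refused early: discrete structures (and
heteroscedastic weights, which are indexed by occasion) require balanced
complete data; an AR order $\ge T$ is rejected as unidentifiable (so AR(2)
is refused at $T = 2$).

## Information criteria and selection

With $k$ counting *all* estimated parameters (fixed effects, correlation
parameters, variance weights, and the scale), and $n_{\mathrm{eff}} = N$
under ML or $N - p$ under REML:

$$ \mathrm{AIC} = -2\ell + 2k, \qquad
   \mathrm{BIC} = -2\ell + k \log n_{\mathrm{eff}}, \qquad
   \mathrm{AICc} = \mathrm{AIC} + \frac{2k(k+1)}{n_{\mathrm{eff}} - k - 1}. $$

The $n_{\mathrm{eff}}$ convention changes BIC values and is stated here
prominently for that reason. AICc is reported as undefined when
$n_{\mathrm{eff}} - k - 1 \le 0$. `compare_structures()` fits a candidate
roster under one mean structure and estimation method — REML by default,
where criteria are comparable because the mean structure is held fixed —
and flags the best fit per criterion among converged fits. The headline
selection uses BIC by convention, with AIC/AICc winners always reported
alongside; this mirrors the common practice of letting the more
parsimonious criterion arbitrate when AIC drifts toward the heavily
parameterized unstructured fit. Ties go to fewer parameters, then to the
lexicographically smaller label. The full-pipeline report also records
whether the diagnostics-based suggestion agrees with the criterion winner.

```{r pipeline}
dataset <- simulate_dataset(simulation_design(
  n_subjects = 100, times = 1:6,
  structure = corr_structure("AR", 0.5), seed = 42))
report <- run_pipeline(dataset, ~ time + group + age)
report
```

## What the simulator emulates — and what it does not

`simulate_dataset()` draws balanced complete designs: outcome
$= X\beta + \varepsilon$ with $\varepsilon$ multivariate normal via the
Cholesky factor of $\sigma^2 D^{1/2} R D^{1/2}$ (a non-positive-definite
assembly is a construction-time error, never silently repaired). The
default battery — intercept 10, linear time effect 0.5, a Bernoulli(0.5)
binary group with effect $-1$, a Normal(40, 10) subject-level age with
effect 0.05, $\sigma^2 = 1$, AR(1) $\phi = 0.5$ on five occasions — was
fixed once as a generic cohort-style stated world (the studies the
simulator emulates do not publish their generator parameters) and is fully
configurable. One root-seeded stream is consumed subject by subject, so
growing `n_subjects` appends subjects without reshuffling earlier ones; an
earlier per-subject-seed scheme based on an arithmetic progression of
Mersenne-Twister seeds was rejected after it produced measurably correlated
draws across subjects.

The generator does **not** emulate dropout or intermittent missingness
(missing cells are a hard load-time error: handle missing data before
analysis), outcome non-normality, time-varying covariates, or
subject-level random effects — the package works with the implied marginal
covariance only. A green recovery or selection test therefore establishes
correctness of the machinery under a correctly specified Gaussian marginal
model, not robustness to misspecification.

## Known limitations

* REML point estimates carry the usual $O(1/n)$ finite-sample bias; at
  $n = 200$ subjects the AR(2) $\phi_2$ estimate is biased by about
  $-0.005$ (indistinguishable from `nlme::gls`), which is visible to a
  200-replicate Monte-Carlo equivalence test even though it is immaterial
  in practice.
* Moving-average, ARMA, ARCH/GARCH and integrated (unit-root) residual
  processes are out of scope, as are spatial semi-variogram methods over
  2-D coordinates and likelihood-ratio testing between structures.
* The continuous-time kinds follow the standard spatial-correlation
  conventions without a nugget term.
* Reports include a wall-clock timestamp only on request
  (`include_timestamp = TRUE`): the default keeps two runs on identical
  inputs byte-identical, which the determinism contract requires.
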