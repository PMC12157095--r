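# Profiled (RE)ML objective, structured fits, information criteria.

test_that("profiled objective equals the dense MVN oracle (ML and REML)", {
  cases <- list(
    list(structure = corr_structure("AR", 0.5), theta = 0.37, delta = NULL),
    list(structure = corr_structure("CS", 0.3), theta = -0.1, delta = NULL),
    list(structure = corr_structure("EXPONENTIAL", 1), theta = 1.7, delta = NULL),
    list(structure = corr_structure("AR", c(0.4, 0.2)), theta = c(0.3, 0.25),
         delta = c(1, 1.4, 0.8, 1.2)))
  for (cs in cases) {
    d <- tiny_dataset(n = 8, T_ = 4, structure = corr_structure("AR", 0.5),
                      seed = 13)
    R <- unclass(build_correlation_matrix(
      corr_structure(cs$structure$kind, cs$theta),
      if (cs$structure$time_domain == "continuous") c(1, 2, 3, 4) else 1:4))[, ]
    for (est in c("ML", "REML")) {
      spec <- marginal_model_spec(~ time + group, cs$structure,
                                  heteroscedastic = !is.null(cs$delta),
                                  estimation = est)
      nll <- neg_log_likelihood(spec, d, cs$theta, variance_weights = cs$delta)
      oracle <- dense_loglik(d, ~ time + group, R, est, delta = cs$delta)
      expect_equal(-nll, oracle, tolerance = 1e-8,
                   label = paste(cs$structure$kind, est))
    }
  }
})

test_that("INDEPENDENT deviance equals the closed-form OLS deviance", {
  d <- tiny_dataset(n = 10, T_ = 4, seed = 19)
  spec <- marginal_model_spec(~ time + group, corr_structure("INDEPENDENT"),
                              estimation = "ML")
  nll <- neg_log_likelihood(spec, d)
  df <- as.data.frame(d)
  X <- model.matrix(~ time + group, df)
  r <- df$outcome - X %*% solve(crossprod(X), crossprod(X, df$outcome))
  N <- length(r)
  s2 <- sum(r^2) / N
  expect_equal(2 * nll, N * log(2 * pi) + N * log(s2) + N, tolerance = 1e-10)
  # CS with rho = 0 collapses to the INDEPENDENT objective
  nll_cs <- neg_log_likelihood(
    marginal_model_spec(~ time + group, corr_structure("CS", 0),
                        estimation = "ML"), d, 0)
  expect_equal(nll_cs, nll, tolerance = 1e-10)
})

test_that("fits agree with the nlme::gls oracle", {
  d <- simulate_dataset(simulation_design(
    n_subjects = 60, times = 1:6, structure = corr_structure("AR", 0.5),
    seed = 11))
  df <- as.data.frame(d)
  for (est in c("REML", "ML")) {
    f <- fit_marginal_model(
      marginal_model_spec(~ time + group + age, corr_structure("AR", 0),
                          estimation = est), d)
    g <- nlme::gls(outcome ~ time + group + age, data = df,
                   correlation = nlme::corAR1(form = ~time | subject),
                   method = est)
    expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
    expect_equal(unname(f$theta),
                 as.numeric(stats::coef(g$modelStruct$corStruct,
                                        unconstrained = FALSE)),
                 tolerance = 1e-4)
    expect_equal(unname(f$beta[, 1]), unname(stats::coef(g)), tolerance = 1e-6)
    expect_equal(f$sigma2, g$sigma^2, tolerance = 1e-4)
  }
  # compound symmetry against gls + corCompSymm
  fc <- fit_marginal_model(
    marginal_model_spec(~ time + group + age, corr_structure("CS", 0),
                        estimation = "REML"), d)
  gc <- nlme::gls(outcome ~ time + group + age, data = df,
                  correlation = nlme::corCompSymm(form = ~1 | subject),
                  method = "REML")
  expect_equal(fc$loglik, as.numeric(stats::logLik(gc)), tolerance = 1e-6)
})

test_that("seeded AR(1) REML fit recovers the generating parameters", {
  d <- simulate_dataset(simulation_design(
    n_subjects = 100, times = 1:6, sigma2 = 1,
    structure = corr_structure("AR", 0.5), seed = 31))
  f <- fit_marginal_model(
    marginal_model_spec(~ time + group + age, corr_structure("AR", 0)), d)
  expect_true(f$converged)
  expect_equal(unname(f$theta), 0.5, tolerance = 0.1)
  expect_equal(f$sigma2, 1, tolerance = 0.2)
})

test_that("INDEPENDENT fit reproduces OLS estimates", {
  d <- tiny_dataset(n = 25, T_ = 4, seed = 23)
  f <- fit_marginal_model(
    marginal_model_spec(~ time + group, corr_structure("INDEPENDENT"),
                        estimation = "ML"), d)
  df <- as.data.frame(d)
  X <- model.matrix(~ time + group, df)
  expect_equal(unname(f$beta[, 1]),
               as.numeric(solve(crossprod(X), crossprod(X, df$outcome))),
               tolerance = 1e-8)
})

test_that("outcome rescaling scales sigma2 and leaves theta unchanged", {
  d <- tiny_dataset(n = 40, T_ = 5, seed = 29)
  f1 <- fit_marginal_model(
    marginal_model_spec(~ time + group, corr_structure("AR", 0)), d)
  df <- as.data.frame(d)
  df$outcome <- df$outcome * 10
  f2 <- fit_marginal_model(
    marginal_model_spec(~ time + group, corr_structure("AR", 0)),
    longitudinal_dataset(df))
  expect_equal(f2$sigma2, 100 * f1$sigma2, tolerance = 1e-4)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-6)
})

test_that("UNSTRUCTURED nests the structured fits (ML log-likelihood)", {
  d <- simulate_dataset(simulation_design(
    n_subjects = 60, times = 1:5, structure = corr_structure("AR", c(0.5, 0.2)),
    seed = 37))
  fits <- lapply(list(corr_structure("AR", 0), corr_structure("CS", 0),
                      corr_structure("INDEPENDENT")), function(s)
    fit_marginal_model(marginal_model_spec(~ time + group, s,
                                           estimation = "ML"), d))
  fu <- fit_marginal_model(
    marginal_model_spec(~ time + group, corr_structure("UNSTRUCTURED"),
                        estimation = "ML"), d)
  for (f in fits) expect_gte(fu$loglik, f$loglik - 1e-3)
})

test_that("heteroscedastic pair recovers weights and satisfies nesting", {
  des <- simulation_design(n_subjects = 200, times = 1:3, sigma2 = 1,
                           structure = corr_structure("CS", 0.3),
                           variance_weights = c(1, 2, 3), seed = 41)
  d <- simulate_dataset(des)
  pair <- fit_heteroscedastic_pair(
    marginal_model_spec(~ time + group + age, corr_structure("CS", 0),
                        estimation = "ML"), d)
  expect_gte(pair$heteroscedastic$loglik, pair$homoscedastic$loglik - 1e-3)
  delta <- pair$heteroscedastic$variance_weights
  expect_equal(delta[1], 1)
  expect_true(delta[3] > delta[2] && delta[2] > delta[1])
  expect_equal(delta, c(1, 2, 3), tolerance = 0.25)
  # null weights: estimates near 1
  des0 <- simulation_design(n_subjects = 200, times = 1:3,
                            structure = corr_structure("CS", 0.3), seed = 43)
  pair0 <- fit_heteroscedastic_pair(
    marginal_model_spec(~ time + group + age, corr_structure("CS", 0),
                        estimation = "ML"), simulate_dataset(des0))
  expect_equal(pair0$heteroscedastic$variance_weights, c(1, 1, 1),
               tolerance = 0.15)
})

test_that("information criteria follow the stated formulas", {
  fake <- structure(list(loglik = -100, n_params = 5, n_eff = 100,
                         converged = TRUE), class = "marginal_fit")
  ic <- information_criteria(fake)
  expect_equal(unname(ic["aic"]), 210)
  expect_equal(unname(ic["bic"]), 200 + 5 * log(100))
  expect_equal(unname(ic["aicc"]), 210 + 2 * 5 * 6 / 94)
  expect_gt(ic["aicc"], ic["aic"])  # positive small-sample correction
  fake_small <- structure(list(loglik = -10, n_params = 9, n_eff = 10,
                               converged = TRUE), class = "marginal_fit")
  expect_warning(ic2 <- information_criteria(fake_small), "AICc undefined")
  expect_true(is.na(ic2["aicc"]))
  fake_nc <- structure(list(loglik = -100, n_params = 5, n_eff = 100,
                            converged = FALSE), class = "marginal_fit")
  expect_warning(information_criteria(fake_nc), "converge")
})

test_that("fit guards: order limits, unbalanced data, rank deficiency", {
  d2 <- tiny_dataset(n = 10, T_ = 2, seed = 47)
  expect_error(fit_marginal_model(
    marginal_model_spec(~ time, corr_structure("AR", c(0, 0))), d2),
    "unidentifiable")
  d <- tiny_dataset(n = 10, T_ = 4, seed = 47)
  dun <- longitudinal_dataset(as.data.frame(d)[-2, ])
  expect_error(fit_marginal_model(
    marginal_model_spec(~ time, corr_structure("AR", 0)), dun),
    "balanced")
  # continuous-time structures accept the unbalanced dataset
  fc <- fit_marginal_model(
    marginal_model_spec(~ time, corr_structure("EXPONENTIAL", 1)), dun)
  expect_true(is.finite(fc$loglik))
  df <- as.data.frame(d); df$time2 <- df$time * 2
  expect_error(fit_marginal_model(
    marginal_model_spec(~ time + time2, corr_structure("AR", 0)),
    longitudinal_dataset(df)), "rank-deficient")
})
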