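# Yule-Walker algebra, PACF, and correlation-matrix construction.

test_that("yw_autocorrelations matches closed forms and the hand-solved system", {
  # AR(1): rho_k = phi^k
  expect_equal(yw_autocorrelations(ar_process(0.6), 3), c(0.6, 0.36, 0.216))
  # AR(2) phi = (0.5, 0.3): 2x2 system solved by hand ->
  # rho1 = 0.5 / (1 - 0.3) = 5/7, rho2 = 0.3 + 0.5 * rho1
  rho <- yw_autocorrelations(ar_process(c(0.5, 0.3)), 2)
  expect_equal(rho, c(5 / 7, 0.3 + 0.5 * 5 / 7), tolerance = 1e-12)
  # white noise: no dependence
  expect_equal(yw_autocorrelations(ar_process(), 4), rep(0, 4))
  expect_true(all(abs(yw_autocorrelations(ar_process(c(0.5, 0.3)), 50)) < 1))
})

test_that("yw_coefficients solves R Phi = Gamma and round-trips", {
  expect_equal(yw_coefficients(c(0.6, 0.36)), c(0.6, 0), tolerance = 1e-12)
  expect_equal(yw_coefficients(0.4), 0.4)
  rho <- yw_autocorrelations(ar_process(c(0.5, 0.3)), 2)
  expect_equal(yw_coefficients(rho), c(0.5, 0.3), tolerance = 1e-10)
  # inconsistent autocorrelations -> non-PD Toeplitz matrix rejected
  expect_error(yw_coefficients(c(0.9, -0.9)), "positive definite")
})

test_that("round trip recovers random stationary coefficients (p <= 5)", {
  set.seed(421)
  for (rep in 1:40) {
    p <- sample(1:5, 1)
    phi <- random_stationary_phi(p)
    rho <- yw_autocorrelations(ar_process(phi), p)
    expect_equal(yw_coefficients(rho), phi, tolerance = 1e-8)
  }
})

test_that("is_stationary uses the characteristic roots with a strict margin", {
  expect_true(is_stationary(0.5)$stationary)
  expect_false(is_stationary(1.0)$stationary)       # unit root
  expect_false(is_stationary(c(0.5, 0.6))$stationary) # phi1 + phi2 >= 1
  expect_true(is_stationary(numeric(0))$stationary)
  st <- is_stationary(0.5)
  expect_equal(Mod(st$roots), 2)
  expect_error(ar_process(1.0), "characteristic roots")
})

test_that("theoretical PACF cuts off after the order", {
  expect_equal(theoretical_pacf(ar_process(0.6), 4), c(0.6, 0, 0, 0))
  # alpha_1 = rho_1, alpha_2 = phi_2 for an AR(2); Durbin-Levinson by hand:
  # alpha_2 = (rho2 - rho1^2) / (1 - rho1^2) = 0.3 for phi = (0.5, 0.3)
  expect_equal(theoretical_pacf(ar_process(c(0.5, 0.3)), 4),
               c(5 / 7, 0.3, 0, 0), tolerance = 1e-12)
  expect_equal(theoretical_pacf(ar_process(), 3), rep(0, 3))
  set.seed(77)
  for (p in 1:4) {
    phi <- random_stationary_phi(p)
    al <- theoretical_pacf(ar_process(phi), p + 3)
    expect_lt(max(abs(al[(p + 1):(p + 3)])), 1e-10)
  }
})

test_that("yw autocorrelations agree with a long simulated series", {
  set.seed(9)
  phi <- c(0.5, 0.3)
  x <- simulate_ar_series(phi, 1e6)
  emp <- stats::acf(x, lag.max = 4, plot = FALSE)$acf[2:5]
  expect_equal(as.numeric(emp),
               yw_autocorrelations(ar_process(phi), 4), tolerance = 0.01)
})

test_that("build_correlation_matrix reproduces the structure formulas", {
  A <- build_correlation_matrix(corr_structure("AR", 0.5), 1:3)
  expect_equal(unclass(A)[, ], 0.5^abs(outer(1:3, 1:3, "-")))
  C <- build_correlation_matrix(corr_structure("CS", 0.3), 1:3)
  expect_equal(unclass(C)[1, 2:3], c(0.3, 0.3))
  expect_equal(diag(unclass(C)[, ]), rep(1, 3))
  # AR(2) bands extend by the Yule-Walker recursion
  rho <- yw_autocorrelations(ar_process(c(0.5, 0.3)), 3)
  B <- unclass(build_correlation_matrix(corr_structure("AR", c(0.5, 0.3)), 1:4))[, ]
  expect_equal(B[1, 2:4], rho, tolerance = 1e-12)
  expect_equal(rho[3], 0.3 * rho[1] + 0.5 * rho[2])
  # continuous kinds on an irregular grid
  tms <- c(0, 0.5, 2, 3.5)
  E <- unclass(build_correlation_matrix(corr_structure("EXPONENTIAL", 2), tms))[, ]
  expect_equal(E[1, 3], exp(-2 / 2))
  G <- unclass(build_correlation_matrix(corr_structure("GAUSSIAN", 2), tms))[, ]
  expect_equal(G[2, 4], exp(-(3 / 2)^2))
  U <- unclass(build_correlation_matrix(
    corr_structure("UNSTRUCTURED", c(0.5, 0.3, 0.4)), 1:3))[, ]
  expect_equal(U[2, 1], 0.5); expect_equal(U[3, 1], 0.3); expect_equal(U[3, 2], 0.4)
})

test_that("correlation matrices are symmetric positive definite with unit diagonal", {
  set.seed(33)
  structures <- list(
    corr_structure("CS", 0.4), corr_structure("AR", random_stationary_phi(3)),
    corr_structure("CAR1", 0.7), corr_structure("EXPONENTIAL", 1.3),
    corr_structure("GAUSSIAN", 2.1), corr_structure("LINEAR", 5),
    corr_structure("SPHERICAL", 4), corr_structure("RATIONAL_QUADRATIC", 1.5),
    corr_structure("INDEPENDENT"))
  for (s in structures) {
    tms <- if (s$time_domain == "continuous") cumsum(runif(5, 0.3, 2)) else 1:5
    R <- unclass(build_correlation_matrix(s, tms))[, ]
    expect_equal(R, t(R))
    expect_equal(diag(R), rep(1, 5))
    expect_true(all(R >= -1 & R <= 1))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("AR(1) and CAR1 agree on an integer equispaced grid", {
  for (phi in c(0.2, 0.5, 0.8)) {
    A <- unclass(build_correlation_matrix(corr_structure("AR", phi), 1:6))[, ]
    C <- unclass(build_correlation_matrix(corr_structure("CAR1", phi), 1:6))[, ]
    expect_equal(A, C, tolerance = 1e-12)
  }
})

test_that("construction guards reject invalid structures and inputs", {
  expect_error(corr_structure("CS", 1.2), "rho")
  expect_error(corr_structure("AR", c(0.5, 0.6)), "non-stationary")
  expect_error(corr_structure("CAR1", 1.5), "\\(0, 1\\)")
  expect_error(corr_structure("EXPONENTIAL", -1), "positive")
  expect_error(build_correlation_matrix(corr_structure("CS", -0.6), 1:3),
               "positive definite")
  expect_error(build_correlation_matrix(corr_structure("AR", 0.5), c(1, 2, 4)),
               "equally spaced")
  expect_error(build_correlation_matrix(
    corr_structure("UNSTRUCTURED", c(0.9, 0.9, -0.9)), 1:3), "positive definite")
  # T = 1 degenerates to [1] for every kind
  for (k in c("CS", "AR", "CAR1", "INDEPENDENT")) {
    M <- build_correlation_matrix(
      corr_structure(k, switch(k, CS = 0.3, AR = 0.5, CAR1 = 0.5, numeric(0))), 1)
    expect_equal(dim(M), c(1L, 1L))
    expect_equal(M[1, 1], 1)
  }
})

test_that("structures round-trip through JSON", {
  for (s in list(corr_structure("AR", c(0.5, 0.3)), corr_structure("CS", 0.4),
                 corr_structure("EXPONENTIAL", 2), corr_structure("INDEPENDENT"))) {
    expect_identical(structure_from_json(structure_to_json(s)), s)
  }
})
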