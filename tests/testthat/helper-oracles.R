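# Independent oracles and fixture builders shared across the suite.
# Every oracle here deliberately takes a different computational route from
# the implementation it checks.

# --- random stationary AR coefficients --------------------------------------
# Draw partial autocorrelations uniformly in (-0.9, 0.9) and expand through
# the Levinson step.  The expansion is re-derived here (independently of the
# package's internal helper) so the round-trip tests do not lean on the code
# under test.
random_stationary_phi <- function(p) {
  alpha <- stats::runif(p, -0.9, 0.9)
  phi <- numeric(0)
  for (a in alpha) phi <- c(phi - a * rev(phi), a)
  phi
}

# --- PACF by successive lag regressions -------------------------------------
# The lag-k partial autocorrelation of a single series is the coefficient of
# x_{t-k} in the least-squares regression of x_t on x_{t-1}..x_{t-k} (with
# intercept).  Solved through the normal equations of the embedded design.
regression_pacf <- function(x, max_lag) {
  E <- embed(x, max_lag + 1L)
  M <- cbind(1, E)                # col 1: intercept, col 2: x_t, 3..: lags
  G <- crossprod(M)
  vapply(seq_len(max_lag), function(k) {
    a_idx <- c(1L, 2L + seq_len(k))
    co <- solve(G[a_idx, a_idx], G[a_idx, 2L])
    co[k + 1L]
  }, numeric(1))
}

# recursive AR(p) series simulation via stats::filter (long burn-in)
simulate_ar_series <- function(phi, n, burn = 1000L) {
  e <- stats::rnorm(n + burn)
  x <- as.numeric(stats::filter(e, phi, method = "recursive"))
  x[(burn + 1L):(burn + n)]
}

# --- dense multivariate-normal likelihood -----------------------------------
# Unprofiled stacked-MVN computation with an explicit dense covariance; used
# to check the profiled per-subject objective.
dense_loglik <- function(dataset, mean_structure, R_subject, estimation,
                         delta = NULL) {
  df <- as.data.frame(dataset)
  roles <- attr(dataset, "roles")
  f <- stats::as.formula(paste(roles["outcome"], "~",
                               paste(deparse(mean_structure[[2]]), collapse = "")))
  X <- stats::model.matrix(f, df)
  y <- df[[roles["outcome"]]]
  N <- length(y)
  p <- ncol(X)
  T_ <- nrow(R_subject)
  W1 <- if (is.null(delta)) R_subject else R_subject * (delta %o% delta)
  n_sub <- N / T_
  W <- kronecker(diag(n_sub), W1)
  Wi <- solve(W)
  beta <- solve(t(X) %*% Wi %*% X, t(X) %*% Wi %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Wi %*% r)
  if (estimation == "ML") {
    s2 <- rss / N
    V <- s2 * W
    as.numeric(-0.5 * (N * log(2 * pi) +
                         determinant(V, logarithm = TRUE)$modulus +
                         t(r) %*% solve(V, r)))
  } else {
    s2 <- rss / (N - p)
    V <- s2 * W
    as.numeric(-0.5 * ((N - p) * log(2 * pi) +
                         determinant(V, logarithm = TRUE)$modulus +
                         determinant(t(X) %*% solve(V, X), logarithm = TRUE)$modulus +
                         t(r) %*% solve(V, r)))
  }
}

# --- small simulated fixtures ------------------------------------------------
tiny_dataset <- function(n = 6, T_ = 4, structure = corr_structure("AR", 0.5),
                         seed = 2, sigma2 = 1, variance_weights = NULL) {
  simulate_dataset(simulation_design(
    n_subjects = n, times = seq_len(T_), sigma2 = sigma2,
    structure = structure, variance_weights = variance_weights, seed = seed))
}

# a fabricated pacf_result, for exercising the suggestion decision rule
fake_pacf <- function(pacf, band, max_lag = length(pacf)) {
  sig <- which(abs(pacf) > band)
  structure(list(lag = seq_along(pacf), pacf = pacf, band = band,
                 suggested_order = if (length(sig)) max(sig) else 0L,
                 n_effective = NA_real_),
            class = "pacf_result")
}

fake_profile <- function(values) {
  structure(data.frame(lag = seq_along(values), mean_correlation = values,
                       n_pairs = rev(seq_along(values))),
            class = c("lag_profile", "data.frame"))
}
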