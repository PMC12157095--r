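# Marginal linear models with structured residual covariance.
#
# The model per subject i is y_i = X_i beta + e_i,
# e_i ~ N(0, sigma2 * D^{1/2} R_i(theta) D^{1/2}), with R_i a correlation
# matrix from the corrstruct families and D = diag(delta_t^2) optional
# per-occasion variance weights.  beta and sigma2 are profiled out
# analytically (GLS beta-hat, RSS-based sigma2-hat), leaving a bounded
# optimization over theta carried out in an unconstrained
# reparameterization: AR coefficients through their partial
# autocorrelations (tanh), CS through a scaled logistic onto
# (-1/(T-1), 1), ranges through log, unstructured correlations through the
# spherical angles of the Cholesky factor, variance weights through log.
#
# For balanced groups the per-evaluation cost is O(T^3 + T^2 p^2): the
# subject sums enter only through precomputed cross-occasion moment
# matrices, so each objective evaluation contracts those moments with
# W^{-1} instead of looping over subjects.

PENALTY <- 1e10

#' Marginal model specification
#'
#' Mean structure, residual correlation structure, heteroscedasticity flag
#' and estimation method for [fit_marginal_model()].
#'
#' @param mean_structure Right-hand-side formula (or string) for the fixed
#'   effects; interactions allowed.
#' @param structure A [corr_structure()] candidate.  For `"AR"` the length
#'   of `params` fixes the order; parameter values act only as metadata
#'   (fits start from the package's deterministic start set).  For
#'   `"UNSTRUCTURED"` the params may be empty; the dimension is taken from
#'   the data.
#' @param heteroscedastic Estimate per-occasion variance weights
#'   `delta_2..delta_T` (`delta_1 = 1`)?  Requires balanced discrete
#'   occasions.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @return An object of class `marginal_spec`.
#' @export
marginal_model_spec <- function(mean_structure, structure,
                                heteroscedastic = FALSE,
                                estimation = c("REML", "ML")) {
  stopifnot(inherits(structure, "corr_structure"))
  estimation <- match.arg(estimation)
  structure(list(mean_structure = mean_structure, structure = structure,
                 heteroscedastic = isTRUE(heteroscedastic),
                 estimation = estimation),
            class = "marginal_spec")
}

# ---- likelihood context -----------------------------------------------------

# Precomputes everything theta-independent: design matrices, grouping of
# subjects by identical time vectors, and per-group cross-occasion moment
# matrices Syy (T x T), SxyM (T^2 x p), SxxM (T^2 x p^2).
likelihood_context <- function(spec, dataset) {
  stopifnot(inherits(spec, "marginal_spec"),
            inherits(dataset, "longitudinal_dataset"))
  roles <- dataset_roles(dataset)
  df <- as.data.frame(dataset)
  f <- as_mean_formula(spec$mean_structure, roles["outcome"])
  X <- stats::model.matrix(f, df)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effects design matrix")
  y <- df[[roles["outcome"]]]
  subj <- df[[roles["subject"]]]
  kind <- spec$structure$kind
  discrete <- spec$structure$time_domain == "discrete_equispaced"
  balanced <- is_balanced(dataset)
  if (discrete && !balanced)
    stop(structure_label(spec$structure), " requires balanced complete data ",
         "on a common occasion grid; use a continuous-time structure for ",
         "unbalanced data")
  if (spec$heteroscedastic && !balanced)
    stop("heteroscedastic variance weights require balanced discrete occasions")
  idx <- split(seq_len(nrow(df)), subj)           # rows already time-ordered
  sig <- vapply(idx, function(ix) paste(signif(df[[roles["time"]]][ix], 12),
                                        collapse = ","), character(1))
  groups <- lapply(split(seq_along(idx), sig), function(g) {
    rows <- idx[g]
    tms <- df[[roles["time"]]][rows[[1]]]
    T_ <- length(tms)
    m <- length(rows)
    p <- ncol(X)
    Y <- matrix(y[unlist(rows)], nrow = m, ncol = T_, byrow = TRUE)
    # occasion-major slices: Xa[[a]] is the m x p covariate matrix at occasion a
    Xflat <- X[unlist(rows), , drop = FALSE]
    occ <- rep(seq_len(T_), times = m)
    Xa <- lapply(seq_len(T_), function(a) Xflat[occ == a, , drop = FALSE])
    Syy <- crossprod(Y)
    SxyM <- matrix(0, T_ * T_, p)
    SxxM <- matrix(0, T_ * T_, p * p)
    for (a in seq_len(T_)) for (b in seq_len(T_)) {
      r <- (b - 1L) * T_ + a
      SxyM[r, ] <- crossprod(Xa[[a]], Y[, b])
      SxxM[r, ] <- as.numeric(crossprod(Xa[[a]], Xa[[b]]))
    }
    # occasion positions on the global grid (for variance weights)
    pos <- match(signif(tms, 12), signif(dataset_times(dataset), 12))
    list(times = tms, m = m, Syy = Syy, SxyM = SxyM, SxxM = SxxM, pos = pos)
  })
  T_glob <- length(dataset_times(dataset))
  if (kind == "AR" && length(spec$structure$params) > T_glob - 1L)
    stop("AR order ", length(spec$structure$params),
         " is unidentifiable with T = ", T_glob, " occasions")
  list(spec = spec, kind = kind, order = length(spec$structure$params),
       n_occ = T_glob, times = dataset_times(dataset),
       groups = groups, X = X, y = y, f = f,
       N = length(y), p = ncol(X),
       n_subjects = length(idx), balanced = balanced,
       estimation = spec$estimation, hetero = spec$heteroscedastic)
}

# correlation-matrix values for a group, given natural parameters
group_R <- function(ctx, params, tms) {
  if (ctx$spec$structure$time_domain == "discrete_equispaced")
    corr_values(ctx$kind, params, seq_along(tms))
  else corr_values(ctx$kind, params, tms)
}

# Core profiled objective: -2 * log-likelihood at natural parameters.
# Returns a penalized value (never NaN) when the implied covariance is not
# positive definite.  attr "pieces" carries beta-hat, sigma2-hat, A for
# reuse by the caller at the optimum.
neg2_loglik_natural <- function(ctx, params, delta = NULL, want_pieces = FALSE) {
  p <- ctx$p
  A <- matrix(0, p, p); cvec <- numeric(p); q <- 0; logdet <- 0
  for (g in ctx$groups) {
    T_ <- length(g$times)
    R <- tryCatch(group_R(ctx, params, g$times), error = function(e) NULL)
    if (is.null(R)) return(PENALTY + sum(params^2))
    if (!is.null(delta)) {
      dg <- delta[g$pos]
      R <- R * (dg %o% dg)
    }
    U <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(U)) return(PENALTY + sum(params^2))
    Winv <- chol2inv(U)
    logdet <- logdet + g$m * 2 * sum(log(diag(U)))
    w <- as.numeric(Winv)
    A <- A + matrix(crossprod(g$SxxM, w), p, p)
    cvec <- cvec + as.numeric(crossprod(g$SxyM, w))
    q <- q + sum(Winv * g$Syy)
  }
  A <- (A + t(A)) / 2
  UA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(UA)) return(PENALTY + sum(params^2))
  beta <- backsolve(UA, forwardsolve(t(UA), cvec))
  rss <- q - sum(cvec * beta)
  if (rss <= 0) return(PENALTY + sum(params^2))
  N <- ctx$N
  if (ctx$estimation == "ML") {
    s2 <- rss / N
    val <- N * log(2 * pi) + N * log(s2) + logdet + N
  } else {
    s2 <- rss / (N - p)
    val <- (N - p) * log(2 * pi) + (N - p) * log(s2) + logdet +
      2 * sum(log(diag(UA))) + (N - p)
  }
  if (want_pieces)
    attr(val, "pieces") <- list(beta = beta, sigma2 = s2, A = A, rss = rss)
  val
}

#' Profiled negative log-likelihood of a marginal model
#'
#' Evaluates the objective minimized by [fit_marginal_model()]: the
#' Gaussian (restricted) log-likelihood with the fixed effects and the
#' scale profiled out analytically (GLS \eqn{\hat\beta(\theta)};
#' \eqn{\hat\sigma^2(\theta)} = RSS/N for ML, RSS/(N-p) for REML), negated.
#' A non-positive-definite covariance yields a large finite penalty, never
#' `NaN`, so optimizers stay in bounds.
#'
#' @param spec A [marginal_model_spec()].
#' @param dataset A [longitudinal_dataset()].
#' @param theta Natural correlation parameters for the spec's structure
#'   (`rho` for CS, `phi` vector for AR, range for the spatial kinds,
#'   lower-triangle correlations for UNSTRUCTURED, empty for INDEPENDENT).
#' @param variance_weights Optional per-occasion multipliers
#'   `delta_1..delta_T` with `delta_1 = 1`; `NULL` for homoscedastic.
#' @return The scalar negative log-likelihood (not the -2 x scale).
#' @export
neg_log_likelihood <- function(spec, dataset, theta = numeric(0),
                               variance_weights = NULL) {
  ctx <- likelihood_context(spec, dataset)
  if (!is.null(variance_weights)) {
    stopifnot(length(variance_weights) == ctx$n_occ,
              abs(variance_weights[1] - 1) < 1e-12)
  }
  as.numeric(neg2_loglik_natural(ctx, as.numeric(theta), variance_weights)) / 2
}

# ---- unconstrained reparameterization ---------------------------------------

n_theta_for <- function(kind, order, T_) {
  switch(kind,
    INDEPENDENT = 0L,
    CS = 1L, CAR1 = 1L,
    EXPONENTIAL = 1L, GAUSSIAN = 1L, LINEAR = 1L, SPHERICAL = 1L,
    RATIONAL_QUADRATIC = 1L,
    AR = order,
    UNSTRUCTURED = as.integer(T_ * (T_ - 1) / 2))
}

# eta (unconstrained) -> natural parameters
eta_to_params <- function(ctx, eta) {
  k <- ctx$kind
  T_ <- ctx$n_occ
  switch(k,
    INDEPENDENT = numeric(0),
    CS = {
      lo <- -1 / (T_ - 1)
      lo + (1 - lo) * stats::plogis(eta)
    },
    AR = pacf_to_ar(tanh(eta)),
    CAR1 = stats::plogis(eta),
    UNSTRUCTURED = {
      ang <- pi * stats::plogis(eta)
      B <- angles_to_cholesky(ang, T_)
      R <- tcrossprod(B)
      t(R)[upper.tri(R)]   # row-major lower triangle
    },
    exp(eta))  # range-parameter kinds
}

# natural parameters -> eta, for start construction
params_to_eta <- function(ctx, params) {
  k <- ctx$kind
  T_ <- ctx$n_occ
  switch(k,
    INDEPENDENT = numeric(0),
    CS = {
      lo <- -1 / (T_ - 1)
      stats::qlogis(pmin(pmax((params - lo) / (1 - lo), 1e-6), 1 - 1e-6))
    },
    AR = atanh(pmin(pmax(ar_to_pacf(params), -0.999), 0.999)),
    CAR1 = stats::qlogis(pmin(pmax(params, 1e-6), 1 - 1e-6)),
    UNSTRUCTURED = {
      R <- corr_values("UNSTRUCTURED", params, seq_len(T_))
      ang <- cholesky_to_angles(R)
      stats::qlogis(pmin(pmax(ang / pi, 1e-6), 1 - 1e-6))
    },
    log(params))
}

# reverse Levinson: AR coefficients -> partial autocorrelations
ar_to_pacf <- function(phi) {
  p <- length(phi)
  alpha <- numeric(p)
  cur <- phi
  for (k in p:1) {
    a <- cur[k]
    alpha[k] <- a
    if (k > 1L) {
      if (abs(1 - a^2) < 1e-12) a <- sign(a) * (1 - 1e-8)
      cur <- (cur[seq_len(k - 1L)] + a * rev(cur[seq_len(k - 1L)])) / (1 - a^2)
    }
  }
  alpha
}

# spherical parameterization of a unit-diagonal Cholesky factor:
# row i of B has entries cos/sin products of angles ang[(i-1)(i-2)/2 + j]
angles_to_cholesky <- function(ang, T_) {
  B <- matrix(0, T_, T_)
  B[1, 1] <- 1
  pos <- 0L
  for (i in 2:T_) {
    s <- 1
    for (j in seq_len(i - 1L)) {
      pos <- pos + 1L
      B[i, j] <- s * cos(ang[pos])
      s <- s * sin(ang[pos])
    }
    B[i, i] <- s
  }
  B
}

cholesky_to_angles <- function(R) {
  T_ <- nrow(R)
  # shrink toward identity until the Cholesky succeeds (sample correlation
  # matrices can be numerically semi-definite)
  lam <- 1
  L <- NULL
  for (it in 1:60) {
    Rs <- lam * R + (1 - lam) * diag(T_)
    L <- tryCatch(t(chol(Rs)), error = function(e) NULL)
    if (!is.null(L)) break
    lam <- lam * 0.95
  }
  if (is.null(L)) return(rep(pi / 2, T_ * (T_ - 1) / 2))
  ang <- numeric(T_ * (T_ - 1) / 2)
  pos <- 0L
  for (i in 2:T_) {
    s <- 1
    for (j in seq_len(i - 1L)) {
      pos <- pos + 1L
      x <- L[i, j] / s
      ang[pos] <- acos(pmin(pmax(x, -1 + 1e-10), 1 - 1e-10))
      s <- s * sin(ang[pos])
      if (s < 1e-10) s <- 1e-10
    }
  }
  ang
}

# ---- deterministic starts ---------------------------------------------------

# three fixed starts per structure: null correlation, moderate positive,
# profile-informed from the naive residual correlation (when available)
start_set <- function(ctx, dataset) {
  k <- ctx$kind
  T_ <- ctx$n_occ
  d1 <- if (length(ctx$times) > 1) min(diff(ctx$times)) else 1
  dbar <- if (length(ctx$times) > 1) mean(diff(ctx$times)) else 1
  lag1 <- NA_real_
  samp_corr <- NULL
  if (ctx$balanced && ctx$n_subjects >= 3) {
    nf <- tryCatch(fit_naive(dataset, ctx$spec$mean_structure),
                   error = function(e) NULL)
    if (!is.null(nf)) {
      rc <- tryCatch(residual_correlation(nf)$correlation,
                     error = function(e) NULL)
      if (!is.null(rc)) {
        samp_corr <- rc
        lag1 <- lag_profile(rc)$mean_correlation[1]
      }
    }
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  starts <- switch(k,
    INDEPENDENT = list(numeric(0)),
    CS = {
      s3 <- if (is.na(lag1)) 0.5 else clamp(lag1, -1 / (T_ - 1) + 0.01, 0.98)
      list(0, 0.3, s3)
    },
    AR = {
      p <- ctx$order
      a2 <- c(0.3, rep(0.1, max(0, p - 1)))
      a3 <- if (is.na(lag1)) a2 else c(clamp(lag1, -0.95, 0.95), rep(0.05, max(0, p - 1)))
      lapply(list(rep(0, p), a2, a3), pacf_to_ar)
    },
    CAR1 = {
      s3 <- if (is.na(lag1)) 0.5 else clamp(lag1, 0.01, 0.99)
      list(0.05, 0.3^(1 / d1), s3^(1 / d1))
    },
    UNSTRUCTURED = {
      # single profile-informed start: with T(T-1)/2 parameters the
      # objective is effectively unimodal around the sample residual
      # correlation, and extra high-dimensional starts triple the cost
      cs_mat <- function(r) { M <- matrix(r, T_, T_); diag(M) <- 1; M }
      tri <- function(M) t(M)[upper.tri(M)]
      if (!is.null(samp_corr)) list(tri(samp_corr))
      else list(tri(cs_mat(0.3)))
    },
    { # range-parameter kinds: small, medium, lag-1 informed
      r3 <- if (!is.na(lag1) && lag1 > 0.01 && lag1 < 0.99) {
        switch(k,
          EXPONENTIAL = -d1 / log(lag1),
          GAUSSIAN = d1 / sqrt(-log(lag1)),
          LINEAR = d1 / (1 - lag1),
          SPHERICAL = 2 * d1 / (1 - lag1),
          RATIONAL_QUADRATIC = d1 * sqrt(lag1 / (1 - lag1)),
          dbar)
      } else dbar
      list(d1 / 4, dbar, max(r3, d1 / 4))
    })
  lapply(starts, function(s) params_to_eta(ctx, s))
}

# ---- fitting ----------------------------------------------------------------

#' Fit a marginal linear model with structured residual covariance
#'
#' Maximizes the (RE)ML likelihood over the correlation parameters (and
#' optional variance weights) by BFGS in an unconstrained
#' reparameterization, from three fixed deterministic starting points
#' (null correlation, moderate positive, informed by the naive residual
#' correlation); the best objective wins, ties broken by smaller parameter
#' norm.  The fit is deterministic given data and spec.  Non-convergence
#' is reported through the `converged` flag, never an exception.
#'
#' @inheritParams neg_log_likelihood
#' @param extra_starts Optional list of additional start values, each a
#'   list with `theta` (natural correlation parameters) and optionally
#'   `delta` (full weight vector, `delta[1] = 1`).
#' @return An object of class `marginal_fit`: fixed effects with standard
#'   errors, `sigma2`, `theta` (natural correlation parameters),
#'   `variance_weights`, `loglik`, `n_obs`, `n_params`, `aic`, `bic`,
#'   `aicc`, `converged`, `optimizer` trace summary, and the fitted
#'   [corr_structure()].
#' @examples
#' d <- simulate_dataset(simulation_design(n_subjects = 40, seed = 7))
#' spec <- marginal_model_spec(~ time + group + age, corr_structure("AR", 0.5))
#' fit_marginal_model(spec, d)
#' @export
fit_marginal_model <- function(spec, dataset, extra_starts = NULL) {
  ctx <- likelihood_context(spec, dataset)
  T_ <- ctx$n_occ
  nth <- n_theta_for(ctx$kind, ctx$order, T_)
  nw <- if (ctx$hetero) T_ - 1L else 0L
  obj <- function(par) {
    eta_t <- par[seq_len(nth)]
    delta <- if (nw > 0L) c(1, exp(par[nth + seq_len(nw)])) else NULL
    params <- eta_to_params(ctx, eta_t)
    as.numeric(neg2_loglik_natural(ctx, params, delta))
  }
  starts <- lapply(start_set(ctx, dataset), function(e) c(e, rep(0, nw)))
  if (nw > 0L && ctx$balanced && ctx$n_subjects >= 3) {
    # profile-informed weights: per-occasion naive residual SD ratios
    nf <- tryCatch(fit_naive(dataset, spec$mean_structure), error = function(e) NULL)
    if (!is.null(nf)) {
      sds <- apply(nf$residual_matrix, 2, stats::sd)
      if (all(sds > 0)) {
        dd <- sds / sds[1]
        starts <- c(starts, list(c(starts[[length(starts)]][seq_len(nth)],
                                   log(dd[-1]))))
      }
    }
  }
  for (ex in extra_starts) {
    e <- params_to_eta(ctx, ex$theta)
    w <- if (nw > 0L) {
      if (is.null(ex$delta)) rep(0, nw) else log(ex$delta[-1])
    } else numeric(0)
    starts <- c(starts, list(c(e, w)))
  }
  best <- NULL
  trace <- character(0)
  for (s in starts) {
    res <- if (length(s) == 0L) {
      list(par = numeric(0), value = obj(numeric(0)), convergence = 0L,
           counts = c(`function` = 1L, gradient = NA))
    } else {
      tryCatch(
        stats::optim(s, obj, method = "BFGS",
                     control = list(reltol = 1e-8, maxit = 500)),
        error = function(e) list(par = s, value = obj(s), convergence = 52L,
                                 counts = c(`function` = NA, gradient = NA)))
    }
    trace <- c(trace, sprintf("start[%s] -> obj %.6f (conv %d)",
                              paste(signif(s, 3), collapse = ","),
                              res$value, res$convergence))
    take <- is.null(best) || res$value < best$value - 1e-9 ||
      (abs(res$value - best$value) <= 1e-9 && sum(res$par^2) < sum(best$par^2))
    if (take) best <- res
  }
  eta_t <- best$par[seq_len(nth)]
  delta <- if (nw > 0L) unname(c(1, exp(best$par[nth + seq_len(nw)]))) else NULL
  params <- eta_to_params(ctx, eta_t)
  val <- neg2_loglik_natural(ctx, params, delta, want_pieces = TRUE)
  pieces <- attr(val, "pieces")
  converged <- best$convergence == 0L && as.numeric(val) < PENALTY / 2
  loglik <- -as.numeric(val) / 2
  se <- sqrt(diag(pieces$sigma2 * chol2inv(chol(pieces$A))))
  beta <- pieces$beta
  names(beta) <- colnames(ctx$X)
  k_par <- ctx$p + nth + nw + 1L
  n_eff <- if (ctx$estimation == "ML") ctx$N else ctx$N - ctx$p
  ic <- ic_values(loglik, k_par, n_eff)
  fitted_structure <- fitted_corr_structure(ctx, params)
  structure(list(
    beta = cbind(estimate = beta, std.error = se),
    sigma2 = pieces$sigma2,
    theta = params,
    variance_weights = delta,
    loglik = loglik, n_obs = ctx$N, n_subjects = ctx$n_subjects,
    n_params = k_par, n_eff = n_eff,
    aic = ic["aic"], bic = ic["bic"], aicc = ic["aicc"],
    converged = converged,
    optimizer = list(trace = trace, value = as.numeric(val),
                     convergence = best$convergence),
    structure = fitted_structure,
    estimation = ctx$estimation,
    heteroscedastic = ctx$hetero,
    spec = spec, formula = ctx$f, times = ctx$times),
    class = "marginal_fit")
}

fitted_corr_structure <- function(ctx, params) {
  if (ctx$kind == "INDEPENDENT") return(corr_structure("INDEPENDENT"))
  tryCatch(corr_structure(ctx$kind, params), error = function(e) {
    s <- ctx$spec$structure
    s$params <- params
    s
  })
}

ic_values <- function(loglik, k, n_eff) {
  aic <- -2 * loglik + 2 * k
  bic <- -2 * loglik + k * log(n_eff)
  aicc <- if (n_eff - k - 1 > 0) aic + 2 * k * (k + 1) / (n_eff - k - 1) else NA_real_
  c(aic = aic, bic = bic, aicc = aicc)
}

#' Information criteria of a fitted marginal model
#'
#' AIC = -2 loglik + 2k; BIC = -2 loglik + k log(n_eff);
#' AICc = AIC + 2k(k+1)/(n_eff - k - 1).  `k` counts all estimated
#' parameters (fixed effects, correlation parameters, variance weights and
#' the scale); `n_eff` is N for ML fits and N - p for REML fits.  AICc is
#' `NA` (with a warning) when `n_eff - k - 1 <= 0`.
#'
#' @param fit A [fit_marginal_model()] result.
#' @return Named numeric vector `c(aic, bic, aicc)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "marginal_fit"))
  if (!fit$converged)
    warning("fit did not converge; information criteria use the best iterate")
  ic <- ic_values(fit$loglik, fit$n_params, fit$n_eff)
  if (is.na(ic["aicc"]))
    warning("AICc undefined: n_eff - k - 1 <= 0")
  ic
}

#' Homoscedastic / heteroscedastic fit pair
#'
#' Fits the same mean and correlation structure twice: once with a common
#' residual variance and once with per-occasion variance weights
#' `delta_2..delta_T` (`delta_1 = 1`).  The heteroscedastic fit includes
#' the homoscedastic optimum (with unit weights) among its starting
#' points, so its log-likelihood can never fall below the homoscedastic
#' one under the same estimation method.
#'
#' @inheritParams neg_log_likelihood
#' @return A list with elements `homoscedastic` and `heteroscedastic`,
#'   both `marginal_fit` objects.
#' @export
fit_heteroscedastic_pair <- function(spec, dataset) {
  homo_spec <- spec; homo_spec$heteroscedastic <- FALSE
  het_spec <- spec; het_spec$heteroscedastic <- TRUE
  homo <- fit_marginal_model(homo_spec, dataset)
  het <- fit_marginal_model(het_spec, dataset,
                            extra_starts = list(list(theta = homo$theta)))
  list(homoscedastic = homo, heteroscedastic = het)
}

#' @export
print.marginal_fit <- function(x, ...) {
  cat("Marginal linear model (", x$estimation, "), structure ",
      structure_label(x$structure),
      if (x$heteroscedastic) " + heteroscedastic weights" else "", "\n", sep = "")
  cat("  ", x$n_subjects, " subjects, ", x$n_obs, " observations",
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  cat("Fixed effects:\n")
  print(round(x$beta, 4))
  cat("sigma2:", format(x$sigma2, digits = 5), "\n")
  if (length(x$theta))
    cat("correlation parameters:",
        paste(format(x$theta, digits = 4), collapse = ", "), "\n")
  if (!is.null(x$variance_weights))
    cat("variance weights:",
        paste(format(x$variance_weights, digits = 4), collapse = ", "), "\n")
  cat(sprintf("logLik %.4f | AIC %.4f | BIC %.4f | AICc %s (k = %d)\n",
              x$loglik, x$aic, x$bic,
              if (is.na(x$aicc)) "NA" else sprintf("%.4f", x$aicc),
              x$n_params))
  invisible(x)
}
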