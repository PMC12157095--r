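# Autoregressive process algebra and correlation-matrix construction.
#
# The AR(p) process x_t = phi_1 x_{t-1} + ... + phi_p x_{t-p} + e_t,
# e_t white noise with variance sigma2, has autocorrelations rho_k tied to
# the coefficients by the Yule-Walker equations
#   rho_k = sum_i phi_i rho_{k-i},
# solvable in either direction.  All correlation structures used elsewhere in
# the package (discrete AR/CS and the continuous-time spatial family) are
# materialized here as explicit T x T correlation matrices.

STATIONARITY_MARGIN <- 1e-8

#' Autoregressive process
#'
#' An AR(p) process defined by its coefficient vector and innovation
#' variance.  Construction enforces stationarity (all characteristic roots
#' strictly outside the unit circle, with a small numerical margin).
#'
#' @param phi Numeric vector of autoregressive coefficients
#'   \eqn{\phi_1,\dots,\phi_p}; `numeric(0)` gives white noise.
#' @param sigma2 Innovation variance, a positive scalar.
#' @return An object of class `ar_process` with fields `order`, `phi`,
#'   `sigma2`.
#' @examples
#' ar_process(c(0.5, 0.3))
#' @export
ar_process <- function(phi = numeric(0), sigma2 = 1) {
  phi <- as.numeric(phi)
  if (anyNA(phi)) stop("'phi' must not contain NA")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || is.na(sigma2) || sigma2 <= 0)
    stop("'sigma2' must be a positive scalar")
  st <- is_stationary(phi)
  if (!st$stationary) {
    bad <- st$roots[Mod(st$roots) <= 1 + STATIONARITY_MARGIN]
    stop("non-stationary AR coefficients; characteristic roots inside/on the unit circle: ",
         paste(format(bad, digits = 6), collapse = ", "))
  }
  structure(list(order = length(phi), phi = phi, sigma2 = sigma2),
            class = "ar_process")
}

#' @export
print.ar_process <- function(x, ...) {
  cat("AR(", x$order, ") process\n", sep = "")
  if (x$order > 0L)
    cat("  phi:   ", paste(format(x$phi, digits = 4), collapse = ", "), "\n", sep = "")
  cat("  sigma2:", format(x$sigma2, digits = 4), "\n")
  invisible(x)
}

#' Stationarity (causality) check for AR coefficients
#'
#' Computes the roots of the characteristic polynomial
#' \eqn{1 - \phi_1 z - \dots - \phi_p z^p} and reports whether all of them
#' lie strictly outside the unit circle (modulus greater than
#' `1 + 1e-8`).  An empty coefficient vector (white noise) is trivially
#' stationary.
#'
#' @param phi Numeric vector of AR coefficients (possibly empty).
#' @return A list with `stationary` (logical flag) and `roots`
#'   (complex vector of characteristic roots, empty for white noise).
#' @examples
#' is_stationary(0.5)$stationary        # TRUE
#' is_stationary(c(0.5, 0.6))$stationary # FALSE: violates phi1 + phi2 < 1
#' @export
is_stationary <- function(phi) {
  phi <- as.numeric(phi)
  if (length(phi) == 0L)
    return(list(stationary = TRUE, roots = complex(0)))
  if (anyNA(phi)) stop("'phi' must not contain NA")
  # drop trailing zeros: they do not change the process but break polyroot
  p <- length(phi)
  while (p > 0L && phi[p] == 0) p <- p - 1L
  if (p == 0L) return(list(stationary = TRUE, roots = complex(0)))
  roots <- polyroot(c(1, -phi[seq_len(p)]))
  list(stationary = all(Mod(roots) > 1 + STATIONARITY_MARGIN), roots = roots)
}

#' Autocorrelations of an AR(p) process via the Yule-Walker equations
#'
#' For lags `k <= p` the autocorrelations solve the exact p x p
#' Yule-Walker linear system; beyond the order they are extended by the
#' recursion \eqn{\rho_k = \sum_i \phi_i \rho_{k-i}}.  Solving the exact
#' system (rather than recursing from guessed initial values) keeps the
#' higher lags consistent with the process.
#'
#' @param process An [ar_process()].
#' @param max_lag Largest lag to return (positive integer).
#' @return Numeric vector `rho[1..max_lag]` of autocorrelations
#'   (`rho_0 = 1` is implied and not returned).
#' @examples
#' yw_autocorrelations(ar_process(0.6), 3)        # 0.6^k
#' yw_autocorrelations(ar_process(c(0.5, 0.3)), 2)
#' @export
yw_autocorrelations <- function(process, max_lag) {
  stopifnot(inherits(process, "ar_process"))
  max_lag <- as.integer(max_lag)
  if (length(max_lag) != 1L || is.na(max_lag) || max_lag < 1L)
    stop("'max_lag' must be a positive integer")
  p <- process$order
  phi <- process$phi
  if (p == 0L) return(rep(0, max_lag))
  # exact linear system in the unknowns rho_1..rho_p:
  # rho_k - sum_i phi_i rho_{|k-i|} = 0, with rho_0 = 1 moved to the RHS
  A <- diag(p)
  b <- numeric(p)
  for (k in seq_len(p)) {
    for (i in seq_len(p)) {
      m <- abs(k - i)
      if (m == 0L) b[k] <- b[k] + phi[i]
      else A[k, m] <- A[k, m] - phi[i]
    }
  }
  rho_p <- solve(A, b)
  rho <- numeric(max_lag)
  rho[seq_len(min(p, max_lag))] <- rho_p[seq_len(min(p, max_lag))]
  if (max_lag > p) {
    full <- c(1, rho_p, numeric(max_lag - p))
    for (k in (p + 1L):max_lag)
      full[k + 1L] <- sum(phi * full[k + 1L - seq_len(p)])
    rho <- full[-1L]
  }
  rho
}

#' AR coefficients from autocorrelations (matrix Yule-Walker)
#'
#' Solves the matrix form \eqn{R\Phi = \Gamma}: `R` is the p x p Toeplitz
#' autocorrelation matrix in `rho[0..p-1]` (with `rho_0 = 1`) and `Gamma`
#' the vector `rho[1..p]`.  The round trip through
#' [yw_autocorrelations()] recovers the coefficients.
#'
#' @param rho Numeric vector of autocorrelations `rho_1..rho_p`.
#' @return Numeric vector of coefficients `phi_1..phi_p`.
#' @examples
#' yw_coefficients(c(0.6, 0.36))  # c(0.6, 0) -- an AR(1) in disguise
#' @export
yw_coefficients <- function(rho) {
  rho <- as.numeric(rho)
  p <- length(rho)
  if (p == 0L) return(numeric(0))
  if (anyNA(rho) || any(abs(rho) >= 1))
    stop("autocorrelations must be finite with |rho_k| < 1")
  # consistency: the full (p+1) x (p+1) Toeplitz matrix of (1, rho_1..rho_p)
  # must be positive definite for rho to be a valid autocorrelation sequence
  ok <- tryCatch({ chol(stats::toeplitz(c(1, rho))); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    stop("autocorrelation matrix is not positive definite; ",
         "the supplied rho sequence is not a valid AR autocorrelation")
  R <- stats::toeplitz(c(1, rho[seq_len(p - 1)])[seq_len(p)])
  as.numeric(solve(R, rho))
}

#' Theoretical partial autocorrelation function of an AR process
#'
#' Runs the Durbin-Levinson recursion on the Yule-Walker autocorrelations.
#' For an AR(p) the PACF cuts off: `alpha_k = 0` for `k > p` (to numerical
#' tolerance), which is what makes the PACF the order-detection tool.
#'
#' @inheritParams yw_autocorrelations
#' @return Numeric vector `alpha[1..max_lag]` of partial autocorrelations.
#' @examples
#' theoretical_pacf(ar_process(c(0.5, 0.3)), 4)  # cuts off after lag 2
#' @export
theoretical_pacf <- function(process, max_lag) {
  stopifnot(inherits(process, "ar_process"))
  max_lag <- as.integer(max_lag)
  if (length(max_lag) != 1L || is.na(max_lag) || max_lag < 1L)
    stop("'max_lag' must be a positive integer")
  if (process$order == 0L) return(rep(0, max_lag))
  rho <- yw_autocorrelations(process, max_lag)
  durbin_levinson(rho)$pacf
}

# Durbin-Levinson recursion on an autocorrelation sequence rho_1..rho_m
# (rho_0 = 1 implied).  Returns the PACF alpha_1..alpha_m and the final
# prediction coefficients phi_1..phi_m.
durbin_levinson <- function(rho) {
  m <- length(rho)
  alpha <- numeric(m)
  phi_prev <- numeric(0)
  v <- 1
  for (k in seq_len(m)) {
    if (k == 1L) a <- rho[1]
    else a <- (rho[k] - sum(phi_prev * rho[(k - 1L):1L])) / v
    # sample sequences without guaranteed positive semidefiniteness can
    # push a partial correlation out of [-1, 1]; clamp and stop
    if (abs(a) > 1) a <- sign(a)
    alpha[k] <- a
    phi_k <- c(phi_prev - a * rev(phi_prev), a)
    v <- v * (1 - a^2)
    if (v <= 0) { # degenerate (|alpha| hit 1): remaining pacf undefined -> 0
      alpha[(k + 1L):m] <- 0
      phi_prev <- phi_k
      break
    }
    phi_prev <- phi_k
  }
  list(pacf = alpha, phi = phi_prev)
}

# Inverse map: partial autocorrelations alpha_1..alpha_p (each in (-1,1))
# to AR coefficients phi_1..phi_p.  Guarantees stationarity, which is why
# the fitting module optimizes AR structures through this map.
pacf_to_ar <- function(alpha) {
  phi <- numeric(0)
  for (a in alpha) phi <- c(phi - a * rev(phi), a)
  phi
}

.str_kinds <- c("CS", "AR", "CAR1", "EXPONENTIAL", "GAUSSIAN", "LINEAR",
                "SPHERICAL", "RATIONAL_QUADRATIC", "UNSTRUCTURED", "INDEPENDENT")
.continuous_kinds <- c("CAR1", "EXPONENTIAL", "GAUSSIAN", "LINEAR",
                       "SPHERICAL", "RATIONAL_QUADRATIC")

#' Residual correlation structure
#'
#' A tagged correlation-structure family with its parameter vector.
#' Discrete kinds (`"CS"`, `"AR"`) assume equally spaced occasions
#' `1..T`; the continuous-time kinds (`"CAR1"`, `"EXPONENTIAL"`,
#' `"GAUSSIAN"`, `"LINEAR"`, `"SPHERICAL"`, `"RATIONAL_QUADRATIC"`) accept
#' arbitrary strictly increasing time coordinates.  `"UNSTRUCTURED"` (the
#' general symmetric correlation, sometimes labelled "symmetry") stores its
#' \eqn{T(T-1)/2} correlations in row-major lower-triangle order.
#'
#' @param kind One of `"CS"`, `"AR"`, `"CAR1"`, `"EXPONENTIAL"`,
#'   `"GAUSSIAN"`, `"LINEAR"`, `"SPHERICAL"`, `"RATIONAL_QUADRATIC"`,
#'   `"UNSTRUCTURED"`, `"INDEPENDENT"`.
#' @param params Numeric parameter vector: the common correlation `rho` for
#'   CS; `phi_1..phi_p` for AR; `phi` in (0,1) for CAR1; a positive range
#'   `r` for the spatial kinds; the lower-triangle correlations for
#'   UNSTRUCTURED; empty for INDEPENDENT.
#' @return An object of class `corr_structure`.
#' @examples
#' corr_structure("AR", c(0.5, 0.3))
#' corr_structure("CS", 0.4)
#' corr_structure("EXPONENTIAL", 2)
#' @export
corr_structure <- function(kind, params = numeric(0)) {
  kind <- toupper(as.character(kind))
  if (kind %in% c("AR1", "AR(1)")) kind <- "AR"
  if (!kind %in% .str_kinds)
    stop("unknown correlation structure kind: ", kind)
  params <- as.numeric(params)
  if (anyNA(params)) stop("structure parameters must not contain NA")
  time_domain <- if (kind %in% .continuous_kinds) "continuous" else "discrete_equispaced"
  switch(kind,
    CS = {
      if (length(params) != 1L) stop("CS takes a single correlation rho")
      if (params >= 1) stop("CS rho must be < 1")
    },
    AR = {
      st <- is_stationary(params)
      if (!st$stationary)
        stop("AR structure coefficients are non-stationary; roots: ",
             paste(format(st$roots, digits = 6), collapse = ", "))
    },
    CAR1 = {
      if (length(params) != 1L || params <= 0 || params >= 1)
        stop("CAR1 phi must lie in (0, 1)")
    },
    UNSTRUCTURED = {
      if (any(abs(params) >= 1)) stop("UNSTRUCTURED correlations must lie in (-1, 1)")
      tn <- (1 + sqrt(1 + 8 * length(params))) / 2
      if (length(params) > 0L && abs(tn - round(tn)) > 1e-9)
        stop("UNSTRUCTURED needs T(T-1)/2 parameters for some integer T")
    },
    INDEPENDENT = {
      if (length(params) != 0L) stop("INDEPENDENT takes no parameters")
    },
    { # continuous range-parameter kinds
      if (length(params) != 1L || params <= 0)
        stop(kind, " takes a single positive range parameter")
    })
  structure(list(kind = kind, params = params, time_domain = time_domain),
            class = "corr_structure")
}

#' @export
print.corr_structure <- function(x, ...) {
  cat("Correlation structure: ", structure_label(x), " [", x$time_domain, "]\n", sep = "")
  if (length(x$params))
    cat("  params: ", paste(format(x$params, digits = 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Human-readable label, e.g. "AR(2)", "CS", "EXPONENTIAL"
structure_label <- function(structure) {
  if (structure$kind == "AR") paste0("AR(", length(structure$params), ")")
  else structure$kind
}

#' Build an explicit correlation matrix for a structure
#'
#' Materializes the T x T correlation matrix of a [corr_structure()] on the
#' given occasion coordinates.  Discrete kinds require `times` to be the
#' equally spaced grid `1..T` (up to a common shift/scale); continuous kinds
#' accept any strictly increasing coordinates.  The result is checked to be
#' symmetric positive definite with unit diagonal.
#'
#' @param structure A [corr_structure()].
#' @param times Numeric vector of occasion coordinates (length T >= 1).
#' @return A `corr_matrix`: the matrix itself with attributes `times` and
#'   class, entries in \[-1, 1\], unit diagonal, all eigenvalues > 0.
#' @examples
#' build_correlation_matrix(corr_structure("AR", 0.5), 1:3)
#' build_correlation_matrix(corr_structure("CS", 0.3), 1:3)
#' @export
build_correlation_matrix <- function(structure, times) {
  stopifnot(inherits(structure, "corr_structure"))
  times <- as.numeric(times)
  T_ <- length(times)
  if (T_ < 1L || anyNA(times)) stop("'times' must be a non-empty numeric vector")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (T_ == 1L)
    return(structure(matrix(1, 1, 1), times = times, class = "corr_matrix"))
  if (structure$time_domain == "discrete_equispaced") {
    d <- diff(times)
    if (max(abs(d - d[1])) > 1e-8 * max(abs(d)))
      stop(structure_label(structure),
           " is a discrete equispaced structure; 'times' must be an equally spaced grid")
  }
  if (structure$kind == "CS" && structure$params <= -1 / (T_ - 1))
    stop("CS rho = ", structure$params, " is not positive definite for T = ",
         T_, " (needs rho > ", format(-1 / (T_ - 1), digits = 4), ")")
  R <- corr_values(structure$kind, structure$params, times)
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop("correlation matrix for ", structure_label(structure),
         " is not positive definite (minimum eigenvalue ",
         format(ev_min, digits = 4), ")")
  structure(R, times = times, class = "corr_matrix")
}

# Lean matrix builder shared by build_correlation_matrix() and the
# likelihood evaluator (no class tagging, no eigendecomposition; callers
# that need a positive-definiteness guarantee check it themselves).
corr_values <- function(kind, p, times) {
  T_ <- length(times)
  D <- abs(outer(times, times, "-"))
  R <- switch(kind,
    INDEPENDENT = diag(T_),
    CS = matrix(p, T_, T_) + diag(1 - p, T_),
    AR = {
      lags <- round(D / (times[2] - times[1]))
      proc <- ar_process(p, 1)
      rho <- c(1, yw_autocorrelations(proc, max(1L, max(lags))))
      matrix(rho[lags + 1L], T_, T_)
    },
    CAR1 = p^D,
    EXPONENTIAL = exp(-D / p),
    GAUSSIAN = exp(-(D / p)^2),
    LINEAR = ifelse(D < p, 1 - D / p, 0),
    SPHERICAL = ifelse(D < p, 1 - 1.5 * (D / p) + 0.5 * (D / p)^3, 0),
    RATIONAL_QUADRATIC = 1 - (D / p)^2 / (1 + (D / p)^2),
    UNSTRUCTURED = {
      need <- T_ * (T_ - 1) / 2
      if (length(p) != need)
        stop("UNSTRUCTURED needs ", need, " parameters for T = ", T_,
             ", got ", length(p))
      M <- diag(T_)
      # row-major lower-triangle order: (2,1), (3,1), (3,2), (4,1), ...
      idx <- which(lower.tri(M), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      M[idx] <- p
      M[upper.tri(M)] <- t(M)[upper.tri(M)]
      M
    },
    stop("unknown kind: ", kind))
  (R + t(R)) / 2
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("Correlation matrix (", nrow(x), " x ", ncol(x), ")\n", sep = "")
  print(unclass(x)[,], ...)
  invisible(x)
}

#' Serialize / deserialize a correlation structure as JSON
#'
#' Round-trippable plain-text representation with fields `kind`, `params`,
#' `time_domain`.
#'
#' @param structure A [corr_structure()].
#' @param json A JSON string or path to a JSON file.
#' @return `structure_to_json()` returns a JSON string;
#'   `structure_from_json()` returns a [corr_structure()].
#' @examples
#' s <- corr_structure("AR", c(0.5, 0.3))
#' identical(structure_from_json(structure_to_json(s)), s)
#' @export
structure_to_json <- function(structure) {
  stopifnot(inherits(structure, "corr_structure"))
  jsonlite::toJSON(list(kind = structure$kind,
                        params = structure$params,
                        time_domain = structure$time_domain),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname structure_to_json
#' @export
structure_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  s <- corr_structure(x$kind, as.numeric(unlist(x$params)))
  if (!is.null(x$time_domain) && !identical(x$time_domain, s$time_domain))
    stop("time_domain '", x$time_domain, "' inconsistent with kind '", x$kind, "'")
  s
}
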