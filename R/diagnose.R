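# Residual-correlation diagnostics of a fixed-effects-only fit.
#
# A model that ignores within-subject correlation leaves that correlation
# in its residuals.  The stage here fits the mean structure by ordinary
# least squares (generalized least squares with identity weights), reshapes
# the residuals into a subjects x occasions matrix, and characterizes their
# correlation two ways: the lag-mean profile of the sample correlation
# matrix (flat => compound symmetry; geometric decay => AR(1)) and a pooled
# partial autocorrelation function whose cutoff lag estimates the AR order.

#' Naive fixed-effects fit (correlation ignored)
#'
#' Fits the mean structure by ordinary least squares -- generalized least
#' squares with identity weights, i.e. no random effects and no residual
#' correlation -- and reshapes the residual vector into an
#' `n_subjects x T` matrix (rows ordered by subject, columns by occasion).
#' Requires balanced complete data, since the reshape needs a full grid.
#'
#' @param dataset A [longitudinal_dataset()].
#' @param mean_structure Right-hand-side formula (or string) for the fixed
#'   effects, e.g. `~ time + group + age`.  The outcome is taken from the
#'   dataset's role map.
#' @return An object of class `naive_fit` with `coefficients` (estimate,
#'   std.error), `residuals`, `residual_matrix`, `model` (the `lm` fit),
#'   `times`.
#' @export
fit_naive <- function(dataset, mean_structure = ~time) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  roles <- dataset_roles(dataset)
  if (!is_balanced(dataset))
    stop("unbalanced data: every subject must be observed at every occasion ",
         "for the residual-matrix diagnostics; complete the data or use ",
         "continuous-time structures in the fitting module directly")
  f <- as_mean_formula(mean_structure, roles["outcome"])
  fit <- stats::lm(f, data = as.data.frame(dataset))
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; collinear term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  res <- stats::residuals(fit)
  tms <- dataset_times(dataset)
  ord <- order(dataset[[roles["subject"]]], dataset[[roles["time"]]])
  rmat <- matrix(res[ord], ncol = length(tms), byrow = TRUE,
                 dimnames = list(NULL, paste0("t", seq_along(tms))))
  cf <- suppressWarnings(summary(fit))$coefficients  # sigma2 = 0 data is legal
  structure(list(coefficients = cf[, 1:2, drop = FALSE],
                 residuals = res, residual_matrix = rmat,
                 model = fit, times = tms, formula = f),
            class = "naive_fit")
}

# "y ~ rhs" from a rhs-only formula or string, with the dataset's outcome
as_mean_formula <- function(mean_structure, outcome) {
  rhs <- if (inherits(mean_structure, "formula")) {
    deparse(mean_structure[[length(mean_structure)]])
  } else as.character(mean_structure)
  rhs <- sub("^\\s*[^~]*~", "", rhs)
  stats::as.formula(paste(outcome, "~", paste(rhs, collapse = "")))
}

#' @export
print.naive_fit <- function(x, ...) {
  cat("Naive fixed-effects fit (OLS, correlation ignored)\n")
  cat("  ", nrow(x$residual_matrix), " subjects x ", ncol(x$residual_matrix),
      " occasions\n", sep = "")
  print(x$coefficients, ...)
  invisible(x)
}

#' Sample correlation of naive-fit residuals across subjects
#'
#' Entry (s, t) is the Pearson correlation, across subjects, between the
#' occasion-s and occasion-t residuals.
#'
#' @param fit A [fit_naive()] result.
#' @return List with `correlation` and `covariance` (both T x T).
#' @export
residual_correlation <- function(fit) {
  stopifnot(inherits(fit, "naive_fit"))
  rmat <- fit$residual_matrix
  if (nrow(rmat) < 3L) stop("need at least 3 subjects")
  v <- apply(rmat, 2, stats::var)
  if (any(v == 0)) stop("zero-variance residual column (degenerate residuals)")
  list(correlation = stats::cor(rmat), covariance = stats::cov(rmat))
}

#' Lag-mean profile of a residual correlation matrix
#'
#' The mean of the k-th off-diagonal of the T x T correlation matrix,
#' plotted against the lag k: flat at rho for compound symmetry, geometric
#' decay for AR(1), the Yule-Walker pattern for higher orders.
#'
#' @param corr A T x T correlation matrix (T >= 2).
#' @return An object of class `lag_profile`: data.frame with `lag`,
#'   `mean_correlation`, `n_pairs`.
#' @export
lag_profile <- function(corr) {
  corr <- as.matrix(corr)
  T_ <- nrow(corr)
  if (T_ < 2L || ncol(corr) != T_) stop("need a square matrix with T >= 2")
  lags <- seq_len(T_ - 1L)
  means <- vapply(lags, function(k) {
    i <- seq_len(T_ - k)
    mean(corr[cbind(i, i + k)])
  }, numeric(1))
  structure(data.frame(lag = lags, mean_correlation = means,
                       n_pairs = T_ - lags),
            class = c("lag_profile", "data.frame"))
}

#' Pooled partial autocorrelation function of naive-fit residuals
#'
#' Pools lag-k cross-products across all subject series, demeaning by the
#' pooled residual mean and dividing by the number of products actually
#' summed, `n * (T - k)`, then runs Durbin-Levinson.  The count-based
#' denominator keeps the pooled autocorrelations consistent as the number
#' of subjects grows (a fixed `n * T` denominator shrinks lag k by
#' `(T - k) / T` forever, which visibly distorts the PACF cutoff at short
#' T); the price is that positive semidefiniteness of the sequence is no
#' longer guaranteed, so the recursion clamps partial correlations into
#' `[-1, 1]` in the rare degenerate case.  The significance band is the white-noise bound
#' `1.96 / sqrt(n * T)`.  The suggested AR order is the length of the
#' initial consecutive run of lags whose |PACF| strictly exceeds the band
#' (0 if lag 1 is inside the band): an AR(p) shows significant spikes up
#' to lag p after which the values drop to zero, so an isolated spurious
#' spike at a longer lag is not read as a higher order.
#'
#' @param fit A [fit_naive()] result.
#' @param max_lag Largest lag, at most T - 1; default `min(T - 1, 10)`.
#' @return An object of class `pacf_result`: list with `lag`, `pacf`,
#'   `band`, `suggested_order`, `n_effective`.
#' @export
pooled_pacf <- function(fit, max_lag = NULL) {
  stopifnot(inherits(fit, "naive_fit"))
  rmat <- fit$residual_matrix
  T_ <- ncol(rmat)
  n <- nrow(rmat)
  if (is.null(max_lag)) max_lag <- min(T_ - 1L, 10L)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag > T_ - 1L)
    stop("'max_lag' must lie in 1..T-1 = 1..", T_ - 1L)
  e <- rmat - mean(rmat)
  gamma <- vapply(0:max_lag, function(k) {
    idx <- seq_len(T_ - k)
    sum(e[, idx, drop = FALSE] * e[, idx + k, drop = FALSE]) / (n * (T_ - k))
  }, numeric(1))
  if (gamma[1] <= 0) stop("degenerate residuals: zero pooled variance")
  rho <- gamma[-1] / gamma[1]
  pacf <- durbin_levinson(rho)$pacf
  band <- 1.96 / sqrt(n * T_)
  sig <- abs(pacf) > band          # boundary equality is non-significant
  run <- which(!sig)               # first non-significant lag ends the run
  order <- if (length(run)) run[1] - 1L else max_lag
  structure(list(lag = seq_len(max_lag), pacf = pacf, band = band,
                 suggested_order = as.integer(order),
                 n_effective = n * T_),
            class = "pacf_result")
}

#' @export
print.pacf_result <- function(x, ...) {
  cat("Pooled residual PACF (band = ", format(x$band, digits = 3),
      ", suggested order = ", x$suggested_order, ")\n", sep = "")
  print(data.frame(lag = x$lag, pacf = round(x$pacf, 4),
                   significant = abs(x$pacf) > x$band), row.names = FALSE)
  invisible(x)
}

#' Suggest a candidate correlation structure from the diagnostics
#'
#' Decision rule: no significant PACF lag -> INDEPENDENT; a single
#' significant lag with a flat lag profile (maximum absolute deviation from
#' its mean below `flatness_tol`) -> CS; a single significant lag with a
#' decaying profile -> AR(1); p >= 2 significant lags -> AR(p).
#'
#' @param profile A [lag_profile()] result.
#' @param pacf A [pooled_pacf()] result from the same fit.
#' @param flatness_tol Flatness threshold on the lag profile
#'   (default 0.05) separating CS from AR(1).
#' @return An object of class `structure_suggestion`: list with `kind`
#'   (`"INDEPENDENT"`, `"CS"` or `"AR"`), `order`, and `evidence`
#'   (flatness statistic, suggested order, band).
#' @export
suggest_structure <- function(profile, pacf, flatness_tol = 0.05) {
  stopifnot(inherits(profile, "lag_profile"), inherits(pacf, "pacf_result"))
  flat_stat <- max(abs(profile$mean_correlation - mean(profile$mean_correlation)))
  p <- pacf$suggested_order
  kind <- if (p == 0L) "INDEPENDENT"
          else if (p == 1L && flat_stat < flatness_tol) "CS"
          else "AR"
  structure(list(kind = kind, order = if (kind == "AR") p else 0L,
                 evidence = list(flatness = flat_stat,
                                 suggested_order = p,
                                 band = pacf$band,
                                 flatness_tol = flatness_tol)),
            class = "structure_suggestion")
}

suggestion_label <- function(s) {
  if (s$kind == "AR") paste0("AR(", s$order, ")") else s$kind
}

#' @export
print.structure_suggestion <- function(x, ...) {
  cat("Suggested residual correlation structure:", suggestion_label(x), "\n")
  cat("  PACF suggested order:", x$evidence$suggested_order,
      "(band", format(x$evidence$band, digits = 3), ")\n")
  cat("  lag-profile flatness:", format(x$evidence$flatness, digits = 3),
      "(tolerance", format(x$evidence$flatness_tol, digits = 3), ")\n")
  invisible(x)
}

#' Export diagnostics as tidy CSV files
#'
#' Writes `lag_profile.csv` (lag, mean_correlation, n_pairs) and
#' `pacf.csv` (lag, pacf, band, significant) into a directory.
#'
#' @param profile A [lag_profile()] result.
#' @param pacf A [pooled_pacf()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
export_diagnostics <- function(profile, pacf, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "lag_profile.csv")
  p2 <- file.path(dir, "pacf.csv")
  utils::write.csv(as.data.frame(profile), p1, row.names = FALSE)
  utils::write.csv(data.frame(lag = pacf$lag, pacf = pacf$pacf,
                              band = pacf$band,
                              significant = abs(pacf$pacf) > pacf$band),
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}
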