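# End-to-end pipeline: load -> naive fit -> diagnostics -> candidate fits
# -> comparison table -> report.

#' Compare candidate residual covariance structures
#'
#' Fits one marginal model per candidate structure (shared mean structure
#' and estimation method) and tabulates log-likelihood, AIC, BIC and AICc.
#' Non-converged fits are kept in the table but excluded from
#' best-flagging.  Ties on a criterion go to the fit with fewer
#' parameters, then to the lexicographically smaller label.
#'
#' @param dataset A [longitudinal_dataset()].
#' @param mean_structure Right-hand-side formula for the fixed effects.
#' @param candidates Non-empty list of [corr_structure()] candidates.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param heteroscedastic Fit every candidate with per-occasion variance
#'   weights?
#' @param criterion Sorting / headline-selection criterion:
#'   `"bic"` (default), `"aic"` or `"aicc"`.
#' @return An object of class `comparison_table`: a data.frame with one
#'   row per candidate (`structure`, `k`, `loglik`, `aic`, `bic`, `aicc`,
#'   `converged`, `best_aic`, `best_bic`, `best_aicc`), attribute `fits`
#'   holding the full `marginal_fit` objects, and attribute `criterion`.
#' @export
compare_structures <- function(dataset, mean_structure, candidates,
                               estimation = c("REML", "ML"),
                               heteroscedastic = FALSE,
                               criterion = c("bic", "aic", "aicc")) {
  estimation <- match.arg(estimation)
  criterion <- match.arg(criterion)
  if (length(candidates) == 0L) stop("empty candidate list")
  fits <- lapply(candidates, function(s) {
    spec <- marginal_model_spec(mean_structure, s,
                                heteroscedastic = heteroscedastic,
                                estimation = estimation)
    fit_marginal_model(spec, dataset)
  })
  labels <- vapply(candidates, structure_label, character(1))
  tab <- data.frame(
    structure = labels,
    k = vapply(fits, function(f) f$n_params, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) unname(f$aic), numeric(1)),
    bic = vapply(fits, function(f) unname(f$bic), numeric(1)),
    aicc = vapply(fits, function(f) unname(f$aicc), numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE)
  for (cr in c("aic", "bic", "aicc")) {
    flag <- rep(FALSE, nrow(tab))
    ok <- which(tab$converged & is.finite(tab[[cr]]))
    if (length(ok)) {
      o <- ok[order(tab[[cr]][ok], tab$k[ok], tab$structure[ok])]
      flag[o[1]] <- TRUE
    }
    tab[[paste0("best_", cr)]] <- flag
  }
  if (!any(tab$converged))
    warning("no candidate fit converged; best flags unset")
  ord <- order(tab[[criterion]], tab$k, tab$structure)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  fits <- fits[ord]
  names(fits) <- tab$structure
  structure(tab, fits = fits, criterion = criterion,
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Model fit comparison (sorted by ", toupper(attr(x, "criterion")),
      ")\n", sep = "")
  df <- as.data.frame(x)
  df$loglik <- round(df$loglik, 2)
  df$aic <- round(df$aic, 2); df$bic <- round(df$bic, 2)
  df$aicc <- round(df$aicc, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

# the structure whose best_<criterion> flag is set (NULL if none converged)
selected_structure <- function(table, criterion = attr(table, "criterion")) {
  col <- paste0("best_", criterion)
  i <- which(table[[col]])
  if (!length(i)) NULL else table$structure[i]
}

# default candidate roster: CS, AR(1)..AR(cap), UNSTRUCTURED, plus the
# continuous kinds when occasions are irregularly spaced
default_candidates <- function(T_, suggested_order, times) {
  cap <- max(1L, min(suggested_order + 1L, T_ - 2L))
  cand <- list(corr_structure("CS", 0))
  for (p in seq_len(cap)) cand <- c(cand, list(corr_structure("AR", rep(0, p))))
  cand <- c(cand, list(corr_structure("UNSTRUCTURED")))
  d <- diff(times)
  if (max(d) - min(d) > 1e-8 * max(abs(d))) {
    cand <- c(cand, list(corr_structure("CAR1", 0.5),
                         corr_structure("EXPONENTIAL", mean(d))))
    # drop the discrete kinds, which need an equispaced grid
    cand <- Filter(function(s) s$time_domain == "continuous", cand)
    cand <- c(cand, list(corr_structure("UNSTRUCTURED")))
  }
  cand
}

#' Run the full selection pipeline
#'
#' Executes the five analysis stages in order: load (or accept) the
#' dataset, fit the naive fixed-effects model, compute the residual
#' diagnostics (lag profile, pooled PACF, structure suggestion), fit the
#' candidate structures, and assemble the comparison table and selected
#' model.  The report records whether the diagnostics-based suggestion
#' agrees with the information-criterion winner.
#'
#' @param dataset A [longitudinal_dataset()], or a CSV path.
#' @param mean_structure Right-hand-side formula for the fixed effects.
#' @param roles Named character vector with entries `subject`, `time`,
#'   `outcome` (used only when `dataset` is a path).
#' @param candidates Optional candidate list; `NULL` auto-populates from
#'   the diagnostics (CS, AR(1)..AR(min(suggested_order + 1, T - 2)),
#'   UNSTRUCTURED; continuous kinds when occasions are irregular).
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param heteroscedastic Fit candidates with per-occasion weights?
#' @param criterion Headline selection criterion (default `"bic"`).
#' @param include_timestamp Record a wall-clock timestamp in the report
#'   metadata?  Off by default so identical inputs give byte-identical
#'   JSON reports.
#' @return An object of class `analysis_report`.
#' @export
run_pipeline <- function(dataset, mean_structure,
                         roles = c(subject = "subject", time = "time",
                                   outcome = "outcome"),
                         candidates = NULL,
                         estimation = c("REML", "ML"),
                         heteroscedastic = FALSE,
                         criterion = c("bic", "aic", "aicc"),
                         include_timestamp = FALSE) {
  estimation <- match.arg(estimation)
  criterion <- match.arg(criterion)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  ds <- stage("load", {
    if (is.character(dataset))
      read_dataset(dataset, subject = roles[["subject"]],
                   time = roles[["time"]], outcome = roles[["outcome"]])
    else { stopifnot(inherits(dataset, "longitudinal_dataset")); dataset }
  })
  nf <- stage("naive-fit", fit_naive(ds, mean_structure))
  diag <- stage("diagnostics", {
    rc <- residual_correlation(nf)
    prof <- lag_profile(rc$correlation)
    pac <- pooled_pacf(nf)
    sug <- suggest_structure(prof, pac)
    list(correlation = rc$correlation, profile = prof, pacf = pac,
         suggestion = sug)
  })
  tms <- dataset_times(ds)
  if (is.null(candidates))
    candidates <- default_candidates(length(tms),
                                     diag$pacf$suggested_order, tms)
  tab <- stage("candidate-fits",
    compare_structures(ds, mean_structure, candidates,
                       estimation = estimation,
                       heteroscedastic = heteroscedastic,
                       criterion = criterion))
  sel <- selected_structure(tab, criterion)
  agreement <- if (is.null(sel)) NA else
    identical(sel, suggestion_label(diag$suggestion))
  rl <- dataset_roles(ds)
  meta <- list(package_version = as.character(utils::packageVersion("longcov")),
               estimation = estimation, criterion = criterion,
               heteroscedastic = heteroscedastic)
  if (include_timestamp) meta$timestamp <- format(Sys.time(), tz = "UTC")
  structure(list(
    dataset_summary = list(
      n_subjects = length(unique(ds[[rl["subject"]]])),
      n_occasions = length(tms), times = tms, n_rows = nrow(ds),
      variables = names(ds)),
    naive_fit = list(coefficients = nf$coefficients),
    diagnostics = diag,
    comparison = tab,
    selected = list(structure = sel, criterion = criterion,
                    agrees_with_suggestion = agreement,
                    suggestion = suggestion_label(diag$suggestion),
                    fit = if (!is.null(sel)) attr(tab, "fits")[[sel]]),
    metadata = meta),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n===============\n")
  cat("Dataset:", x$dataset_summary$n_subjects, "subjects x",
      x$dataset_summary$n_occasions, "occasions\n\n")
  print(x$diagnostics$suggestion)
  cat("\n")
  print(x$comparison)
  cat("\nSelected by ", toupper(x$selected$criterion), ": ",
      x$selected$structure,
      if (isTRUE(x$selected$agrees_with_suggestion))
        " (agrees with the residual diagnostics)"
      else paste0(" (diagnostics suggested ", x$selected$suggestion, ")"),
      "\n", sep = "")
  invisible(x)
}

report_as_list <- function(report) {
  tab <- as.data.frame(report$comparison)
  sel_fit <- report$selected$fit
  list(
    dataset_summary = report$dataset_summary,
    naive_fit = list(coefficients = as.data.frame(cbind(
      term = rownames(report$naive_fit$coefficients),
      as.data.frame(report$naive_fit$coefficients)))),
    diagnostics = list(
      lag_profile = as.data.frame(report$diagnostics$profile),
      pacf = data.frame(lag = report$diagnostics$pacf$lag,
                        pacf = report$diagnostics$pacf$pacf,
                        band = report$diagnostics$pacf$band),
      suggested_order = report$diagnostics$pacf$suggested_order,
      suggestion = suggestion_label(report$diagnostics$suggestion)),
    comparison = tab,
    selected = list(
      structure = report$selected$structure,
      criterion = report$selected$criterion,
      agrees_with_suggestion = report$selected$agrees_with_suggestion,
      suggestion = report$selected$suggestion,
      fit = if (is.null(sel_fit)) NULL else list(
        beta = data.frame(term = rownames(sel_fit$beta),
                          estimate = sel_fit$beta[, 1],
                          std.error = sel_fit$beta[, 2]),
        sigma2 = sel_fit$sigma2,
        theta = sel_fit$theta,
        variance_weights = sel_fit$variance_weights,
        loglik = sel_fit$loglik,
        aic = unname(sel_fit$aic), bic = unname(sel_fit$bic),
        aicc = unname(sel_fit$aicc),
        converged = sel_fit$converged)),
    metadata = report$metadata)
}

#' Write an analysis report
#'
#' `"json"` is the canonical machine-readable format; `"csv-bundle"`
#' writes one CSV per table into a directory; `"markdown"` renders a
#' human-readable summary.  All three serialize the same in-memory report
#' with no recomputation.
#'
#' @param report An [run_pipeline()] result.
#' @param path Output file (json, markdown) or directory (csv-bundle).
#' @param format One of `"json"`, `"csv-bundle"`, `"markdown"`.
#' @return Invisibly, the path(s) written.
#' @export
write_report <- function(report, path, format = c("json", "csv-bundle", "markdown")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  x <- report_as_list(report)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(path))
  }
  if (format == "csv-bundle") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- c(
      naive_coefficients = "naive_coefficients.csv",
      lag_profile = "lag_profile.csv",
      pacf = "pacf.csv",
      comparison = "comparison.csv")
    utils::write.csv(x$naive_fit$coefficients,
                     file.path(path, files[1]), row.names = FALSE)
    utils::write.csv(x$diagnostics$lag_profile,
                     file.path(path, files[2]), row.names = FALSE)
    utils::write.csv(x$diagnostics$pacf,
                     file.path(path, files[3]), row.names = FALSE)
    utils::write.csv(x$comparison, file.path(path, files[4]), row.names = FALSE)
    return(invisible(file.path(path, files)))
  }
  # markdown
  lines <- c(
    "# Longitudinal covariance-structure analysis", "",
    sprintf("- subjects: %d", x$dataset_summary$n_subjects),
    sprintf("- occasions: %d", x$dataset_summary$n_occasions),
    sprintf("- suggested structure (residual diagnostics): %s",
            x$diagnostics$suggestion),
    sprintf("- selected structure (%s): %s",
            toupper(x$selected$criterion),
            if (is.null(x$selected$structure)) "none (no converged fit)"
            else x$selected$structure), "",
    "## Model fit comparison", "",
    "| structure | k | loglik | AIC | BIC | AICc | converged |",
    "|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(x$comparison)), function(i) {
      r <- x$comparison[i, ]
      sprintf("| %s | %d | %.2f | %.2f | %.2f | %.2f | %s |",
              r$structure, as.integer(r$k), r$loglik, r$aic, r$bic, r$aicc,
              r$converged)
    }, character(1)), "")
  writeLines(lines, path)
  invisible(path)
}
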