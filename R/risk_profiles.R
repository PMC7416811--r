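#' Build per-patient risk profiles from per-biomarker Cox models
#'
#' For each biomarker scope, runs the stepwise-AIC Cox selection
#' ([stepwise_aic()]) and evaluates the centred linear predictor
#' ([linear_predictor()]); the per-model predictors are concatenated
#' column-wise into the patient-by-biomarker risk-profile matrix that feeds
#' consensus clustering. Because every model contains the scope's confounders
#' as candidate terms (and the biomarker itself is forced), each column is a
#' confounder-adjusted risk score for its biomarker. Columns are z-scored by
#' default so models with different coefficient scales contribute comparably;
#' a zero-variance column is a hard error naming the biomarker.
#'
#' @param cohort Cohort data frame.
#' @param scopes List of [model_scope()]s (e.g. [default_scopes()]), one per
#'   biomarker.
#' @param scaling `"zscore"` (default) or `"none"`.
#' @param ties,time_col,event_col Passed to the Cox fits.
#' @return A `risk_profile_matrix`: `profiles` (tibble `patient_id` + one
#'   column per biomarker), `fits` (named list of `cox_fit`s), `biomarkers`,
#'   `scaling`.
#' @export
build_risk_profiles <- function(cohort, scopes, scaling = c("zscore", "none"),
                                ties = "efron",
                                time_col = "time", event_col = "event") {
  scaling <- match.arg(scaling)
  rc_assert(length(scopes) >= 1, "at least one model scope is required")
  biomarkers <- vapply(scopes, function(s) s$biomarker, character(1))
  fits <- list()
  cols <- list()
  for (i in seq_along(scopes)) {
    bm <- biomarkers[i]
    fit <- tryCatch(
      stepwise_aic(cohort, scopes[[i]], ties = ties,
                   time_col = time_col, event_col = event_col),
      error = function(e) {
        rc_abort(sprintf("risk-profile model for biomarker `%s` failed: %s",
                         bm, conditionMessage(e)))
      })
    if (!any(fit$assign == bm)) {
      rc_abort(sprintf(
        "biomarker `%s` carries no coefficient in its risk model (constant or dropped column)",
        bm))
    }
    eta <- linear_predictor(fit, cohort)
    if (sd(eta) < 1e-12) {
      rc_abort(sprintf(
        "biomarker `%s` produced a degenerate (zero-variance) risk column", bm))
    }
    if (scaling == "zscore") eta <- (eta - mean(eta)) / sd(eta)
    fits[[bm]] <- fit
    cols[[bm]] <- eta
  }
  ids <- if ("patient_id" %in% names(cohort)) {
    as.character(cohort$patient_id)
  } else {
    as.character(seq_len(nrow(cohort)))
  }
  profiles <- dplyr::bind_cols(tibble::tibble(patient_id = ids),
                               tibble::as_tibble(cols))
  structure(list(profiles = profiles, fits = fits,
                 biomarkers = unname(biomarkers), scaling = scaling),
            class = "risk_profile_matrix")
}

#' @export
print.risk_profile_matrix <- function(x, ...) {
  cat(sprintf("<risk_profile_matrix> %d patients x %d biomarker models (scaling = %s)\n",
              nrow(x$profiles), length(x$biomarkers), x$scaling))
  print(x$profiles, ...)
  invisible(x)
}

#' @method as_tibble risk_profile_matrix
#' @export
as_tibble.risk_profile_matrix <- function(x, ...) x$profiles

#' Per-model selection summary of a risk-profile build
#'
#' @param x A `risk_profile_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per biomarker model: selected terms, AIC,
#'   number of events, convergence flag.
#' @method tidy risk_profile_matrix
#' @export
tidy.risk_profile_matrix <- function(x, ...) {
  dplyr::bind_rows(lapply(x$biomarkers, function(bm) {
    fit <- x$fits[[bm]]
    tibble::tibble(biomarker = bm,
                   terms = paste(fit$terms, collapse = " + "),
                   n_terms = length(fit$beta), AIC = fit$aic,
                   n_events = fit$n_events, converged = fit$converged)
  }))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
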