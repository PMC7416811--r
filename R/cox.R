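# ---- design-matrix construction ------------------------------------------
# Terms are column names of the cohort, or interactions "a:b". Categorical
# variables are reference-coded against the first level in sorted order; an
# interaction of a numeric biomarker with a categorical confounder expands to
# one product column per non-reference level.

is_interaction <- function(term) grepl(":", term, fixed = TRUE)

term_variables <- function(terms) {
  unique(unlist(strsplit(terms, ":", fixed = TRUE)))
}

encode_variable <- function(data, var, xlevels) {
  x <- data[[var]]
  if (is.null(x)) rc_abort(sprintf("column `%s` not found in cohort", var),
                           class = "riskclust_missing_column")
  if (is.numeric(x)) {
    m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, var))
    return(list(mat = m, levels = NULL))
  }
  x <- as.character(x)
  levs <- xlevels[[var]] %||% sort(unique(x))
  bad <- setdiff(unique(x), levs)
  if (length(bad) > 0) {
    rc_abort(sprintf("column `%s` has unseen level(s): %s", var,
                     paste(bad, collapse = ", ")))
  }
  if (length(levs) < 2) {
    return(list(mat = matrix(numeric(nrow(data)), ncol = 0,
                             dimnames = list(NULL, character())),
                levels = levs))
  }
  m <- vapply(levs[-1], function(l) as.numeric(x == l), numeric(length(x)))
  colnames(m) <- paste0(var, levs[-1])
  list(mat = m, levels = levs)
}

# returns list(X, assign = term per column, xlevels)
build_design <- function(data, terms, xlevels = list()) {
  n <- nrow(data)
  blocks <- list(); assign <- character(); out_levels <- list()
  enc <- list()
  for (v in term_variables(terms)) {
    enc[[v]] <- encode_variable(data, v, xlevels)
    if (!is.null(enc[[v]]$levels)) out_levels[[v]] <- enc[[v]]$levels
  }
  for (term in terms) {
    vars <- strsplit(term, ":", fixed = TRUE)[[1]]
    m <- enc[[vars[1]]]$mat
    if (length(vars) > 1) {
      for (v in vars[-1]) {
        other <- enc[[v]]$mat
        if (ncol(m) == 0 || ncol(other) == 0) {
          m <- matrix(numeric(n), ncol = 0, dimnames = list(NULL, character()))
          next
        }
        cols <- list()
        for (i in seq_len(ncol(m))) for (j in seq_len(ncol(other))) {
          cols[[paste0(colnames(m)[i], ":", colnames(other)[j])]] <-
            m[, i] * other[, j]
        }
        m <- do.call(cbind, cols)
      }
    }
    if (is.null(dim(m))) m <- matrix(m, ncol = 1, dimnames = list(NULL, term))
    blocks[[term]] <- m
    assign <- c(assign, rep(term, ncol(m)))
  }
  X <- do.call(cbind, blocks)
  if (is.null(X)) X <- matrix(numeric(n), ncol = 0)
  list(X = X, assign = assign, xlevels = out_levels)
}

# ---- Efron / Breslow partial likelihood ----------------------------------
# Pre-sorted structure reused across Newton-Raphson iterations. Rows are
# sorted by time ascending; `s_idx[k]` is the first row of the risk set at the
# k-th death time, `death_rows` the rows of the observed deaths (grouped by
# death time via `death_group`, with the Efron fraction `efron_frac` = (l-1)/d
# for the l-th death in a tie group).
cox_prepare <- function(time, event, X) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  death_times <- unique(time[event == 1])
  n <- length(time)
  K <- length(death_times)
  s_idx <- n + 1L - findInterval(-death_times, rev(-time))
  death_rows <- which(event == 1)
  death_group <- match(time[death_rows], death_times)
  d_sizes <- tabulate(death_group, nbins = K)
  efron_frac <- unlist(lapply(d_sizes, function(d) (seq_len(d) - 1) / d))
  # packed upper-triangle index pairs for the second-moment accumulators
  p <- ncol(X)
  pairs <- if (p > 0) which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
           else matrix(integer(), 0, 2)
  list(time = time, event = event, X = X, ord = ord,
       death_times = death_times, s_idx = s_idx, death_rows = death_rows,
       death_group = death_group, d_sizes = d_sizes, efron_frac = efron_frac,
       pair_i = pairs[, 1], pair_j = pairs[, 2])
}

rev_cumsum <- function(v) rev(cumsum(rev(v)))

unpack_sym <- function(v, p, pair_i, pair_j) {
  M <- matrix(0, p, p)
  M[cbind(pair_i, pair_j)] <- v
  M[cbind(pair_j, pair_i)] <- v
  M
}

# log partial likelihood, gradient and observed information at beta,
# vectorised across event times (Efron handled through per-death fractions)
cox_loglik <- function(prep, beta, ties = "efron", what = "all") {
  X <- prep$X
  p <- ncol(X)
  n <- nrow(X)
  eta <- if (p > 0) drop(X %*% beta) else numeric(n)
  w <- exp(eta)
  dr <- prep$death_rows
  g <- prep$death_group
  f <- if (ties == "efron") prep$efron_frac else numeric(length(dr))
  RS0 <- rev_cumsum(w)
  S0 <- RS0[prep$s_idx]                 # per death time
  wD0 <- drop(rowsum(w[dr], g))
  den <- S0[g] - f * wD0[g]             # per death (Efron fraction applied)
  ll <- sum(eta[dr]) - sum(log(den))
  if (!is.finite(ll) || p == 0 || what != "all") {
    return(list(loglik = ll, grad = numeric(p), info = matrix(0, p, p)))
  }
  wX <- w * X
  RS1 <- apply(wX, 2, rev_cumsum)
  S1 <- RS1[prep$s_idx, , drop = FALSE]
  wD1 <- rowsum(wX[dr, , drop = FALSE], g)
  Z1 <- (S1[g, , drop = FALSE] - f * wD1[g, , drop = FALSE]) / den
  grad <- colSums(X[dr, , drop = FALSE]) - colSums(Z1)
  P2 <- X[, prep$pair_i, drop = FALSE] * wX[, prep$pair_j, drop = FALSE]
  RS2 <- apply(P2, 2, rev_cumsum)
  S2 <- RS2[prep$s_idx, , drop = FALSE]
  wD2 <- rowsum(P2[dr, , drop = FALSE], g)
  Z2 <- (S2[g, , drop = FALSE] - f * wD2[g, , drop = FALSE]) / den
  info <- unpack_sym(colSums(Z2), p, prep$pair_i, prep$pair_j) - crossprod(Z1)
  list(loglik = ll, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model by partial-likelihood maximisation
#'
#' Newton-Raphson maximisation of the Cox log partial likelihood with the
#' Efron (default) or Breslow correction for tied event times, iterated to a
#' gradient max-norm below `tol` (default 1e-8, at most `max_iter` steps, with
#' step-halving). Categorical covariates are reference-coded against the first
#' level in sorted order; `"a:b"` terms denote interactions. Rows with missing
#' values in any used column are dropped (complete-case), with an error if more
#' than 20% of patients would be lost. The covariance is the inverse observed
#' information.
#'
#' @param cohort Data frame with survival columns and covariates.
#' @param terms Character vector of model terms (column names, plus optional
#'   `"biomarker:confounder"` interactions).
#' @param ties `"efron"` or `"breslow"`.
#' @param time_col,event_col Names of the survival time (months) and event
#'   indicator (1 = event, 0 = censored) columns.
#' @param tol,max_iter Newton-Raphson convergence controls.
#' @return A `cox_fit` object: `terms`, `beta` (named log hazard ratios),
#'   `covariance`, `loglik`, `loglik_null`, `aic`, `n`, `n_events`, `ties`,
#'   `converged`, plus the design coding needed by [linear_predictor()].
#' @seealso [tidy.cox_fit()], [glance.cox_fit()], [test_ph()]
#' @export
fit_cox <- function(cohort, terms, ties = c("efron", "breslow"),
                    time_col = "time", event_col = "event",
                    tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  rc_assert(length(terms) >= 1, "at least one model term is required")
  vars <- term_variables(terms)
  missing_cols <- setdiff(c(time_col, event_col, vars), names(cohort))
  if (length(missing_cols) > 0) {
    rc_abort(sprintf("cohort is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "riskclust_missing_column")
  }
  used <- cohort[, c(time_col, event_col, vars), drop = FALSE]
  keep <- complete.cases(used)
  if (mean(keep) < 0.8) {
    rc_abort(sprintf(
      "complete-case filtering would drop %.0f%% of patients (limit 20%%)",
      100 * (1 - mean(keep))))
  }
  cohort <- cohort[keep, , drop = FALSE]
  time <- as.numeric(cohort[[time_col]])
  event <- as.integer(cohort[[event_col]])
  rc_assert(all(time > 0), "survival times must be strictly positive")
  rc_assert(all(event %in% c(0L, 1L)), "event indicator must be 0/1")
  if (sum(event) == 0) rc_abort("no events in cohort; cannot fit Cox model",
                                class = "riskclust_no_events")
  des <- build_design(cohort, terms)
  X <- des$X
  # drop constant columns, then demand full rank
  keep_col <- apply(X, 2, function(x) diff(range(x)) > 0)
  X <- X[, keep_col, drop = FALSE]
  assign <- des$assign[keep_col]
  if (ncol(X) == 0) rc_abort("design matrix has no non-constant columns")
  qrX <- qr(scale(X, scale = FALSE))
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rc_abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                     paste(bad, collapse = ", ")),
             class = "riskclust_rank_deficient")
  }
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  prep <- cox_prepare(time, event, Xc)
  p <- ncol(Xc)
  beta <- numeric(p)
  cur <- cox_loglik(prep, beta, ties)
  loglik_null <- cur$loglik
  converged <- FALSE
  diagnostic <- NULL
  for (iter in seq_len(max_iter)) {
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step)) { diagnostic <- "singular information matrix"; break }
    new_beta <- beta + step
    new <- cox_loglik(prep, new_beta, ties)
    halvings <- 0
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik) && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new <- cox_loglik(prep, new_beta, ties)
      halvings <- halvings + 1
    }
    beta <- new_beta
    cur <- new
    if (max(abs(beta)) > 20) {
      diagnostic <- "monotone likelihood suspected (diverging coefficient)"
      break
    }
  }
  if (!converged && max(abs(cur$grad)) < tol) converged <- TRUE
  if (!converged && is.null(diagnostic)) diagnostic <- "max iterations reached"
  covariance <- tryCatch(solve(cur$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(covariance) <- list(colnames(Xc), colnames(Xc))
  structure(list(
    terms = terms, assign = assign,
    beta = setNames(drop(beta), colnames(Xc)),
    covariance = covariance,
    loglik = cur$loglik, loglik_null = loglik_null,
    aic = -2 * cur$loglik + 2 * p,
    n = length(time), n_events = sum(event),
    ties = ties, converged = converged, diagnostic = diagnostic,
    centers = centers, xlevels = des$xlevels,
    time_col = time_col, event_col = event_col),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d patients, %d events, ties = %s%s\n",
              x$n, x$n_events, x$ties,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(tidy(x), ...)
  cat(sprintf("log partial likelihood = %.4f, AIC = %.4f\n", x$loglik, x$aic))
  invisible(x)
}

#' Tidy a fitted Cox model
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate` (log
#'   hazard ratio), `std.error`, `statistic` (Wald z), `p.value`.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  se <- sqrt(diag(x$covariance))
  z <- x$beta / se
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = unname(se), statistic = unname(z),
                 p.value = unname(2 * pnorm(-abs(z))))
}

#' One-row summary of a fitted Cox model
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_events`, `logLik`, `logLik_null`, `AIC`,
#'   `n_terms`, `converged`.
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, logLik = x$loglik,
                 logLik_null = x$loglik_null, AIC = x$aic,
                 n_terms = length(x$beta), converged = x$converged)
}

#' Per-patient linear predictor of a fitted Cox model
#'
#' Evaluates \eqn{\eta_i = x_i \beta} with the fit's design coding (reference
#' levels, interaction expansion) on a cohort, then centres \eqn{\eta} to mean
#' zero over that cohort so that concatenated risk profiles are location-free.
#'
#' @param fit A `cox_fit`.
#' @param cohort Data frame containing every column the fit's terms use.
#' @return Numeric vector of centred linear predictors, one per row of
#'   `cohort`.
#' @export
linear_predictor <- function(fit, cohort) {
  des <- build_design(cohort, fit$terms, xlevels = fit$xlevels)
  X <- des$X[, names(fit$beta), drop = FALSE]
  eta <- drop(X %*% fit$beta)
  eta - mean(eta)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
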