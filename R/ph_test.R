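# Schoenfeld residuals, one row per observed death (ascending death time).
# With Efron ties the l-th death in a tie group uses the Efron-adjusted
# risk-set mean; with Breslow all tied deaths share the full risk-set mean.
schoenfeld_residuals <- function(prep, beta, ties = "efron") {
  time <- prep$time; event <- prep$event; X <- prep$X
  p <- ncol(X)
  w <- exp(drop(X %*% beta))
  dt <- rev(prep$death_times)
  n <- length(time)
  i <- n
  S0 <- 0; S1 <- numeric(p)
  out <- list(); out_t <- numeric()
  for (tk in dt) {
    while (i >= 1 && time[i] >= tk) {
      S0 <- S0 + w[i]
      S1 <- S1 + w[i] * X[i, ]
      i <- i - 1
    }
    D <- which(time == tk & event == 1)
    d <- length(D)
    wD0 <- sum(w[D])
    XD <- X[D, , drop = FALSE]
    wD1 <- drop(crossprod(XD, w[D]))
    res <- matrix(NA_real_, d, p)
    for (l in seq_len(d)) {
      f <- if (ties == "efron") (l - 1) / d else 0
      res[l, ] <- XD[l, ] - (S1 - f * wD1) / (S0 - f * wD0)
    }
    out[[length(out) + 1]] <- res
    out_t <- c(out_t, rep(tk, d))
  }
  ord <- order(out_t)
  list(residuals = do.call(rbind, out)[ord, , drop = FALSE],
       death_times = out_t[ord])
}

ph_time_transform <- function(times, events, death_times, transform) {
  switch(transform,
    identity = death_times,
    rank = rank(death_times, ties.method = "average"),
    km = {
      km <- km_compute(times, events)
      # left-continuous KM just before each death time
      surv_before <- vapply(death_times, function(t) {
        prior <- km$survival[km$time < t]
        if (length(prior) == 0) 1 else prior[length(prior)]
      }, numeric(1))
      1 - surv_before
    })
}

#' Grambsch-Therneau test of the proportional-hazards assumption
#'
#' Score test for a time trend in the scaled Schoenfeld residuals of a fitted
#' Cox model. Event times are transformed (default: the overall Kaplan-Meier
#' scale, `1 - S(t-)`), centred, and correlated with the Schoenfeld residuals;
#' the per-coefficient and global statistics are referred to chi-square
#' distributions with 1 and \eqn{p} degrees of freedom, using the average
#' observed information as the within-time covariance approximation.
#'
#' @param fit A converged `cox_fit`.
#' @param cohort The cohort the fit was estimated on.
#' @param transform Time transform: `"km"` (default), `"identity"` or
#'   `"rank"`.
#' @return A `ph_test` object with `$table` (tibble: term, chisq, df, p.value,
#'   the final row `GLOBAL`), `$transform`, and `$global_p`.
#' @export
test_ph <- function(fit, cohort, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  rc_assert(inherits(fit, "cox_fit"), "`fit` must be a cox_fit")
  rc_assert(isTRUE(fit$converged), "PH test requires a converged fit")
  vars <- term_variables(fit$terms)
  used <- cohort[, c(fit$time_col, fit$event_col, vars), drop = FALSE]
  cohort <- cohort[complete.cases(used), , drop = FALSE]
  time <- as.numeric(cohort[[fit$time_col]])
  event <- as.integer(cohort[[fit$event_col]])
  if (sum(event) < 2) rc_abort("PH test needs at least 2 events")
  des <- build_design(cohort, fit$terms, xlevels = fit$xlevels)
  X <- des$X[, names(fit$beta), drop = FALSE]
  Xc <- sweep(X, 2, fit$centers)
  prep <- cox_prepare(time, event, Xc)
  sr <- schoenfeld_residuals(prep, fit$beta, ties = fit$ties)
  g <- ph_time_transform(time, event, sr$death_times, transform)
  gc <- g - mean(g)
  d <- length(gc)
  info <- cox_loglik(prep, fit$beta, ties = fit$ties)$info
  vinv <- solve(info)  # I^{-1}
  u <- drop(crossprod(sr$residuals, gc))
  ssg <- sum(gc^2)
  vu <- drop(vinv %*% u)
  per_term <- d * vu^2 / (diag(vinv) * ssg)
  global <- d * sum(u * vu) / ssg
  p <- length(u)
  table <- tibble::tibble(
    term = c(names(fit$beta), "GLOBAL"),
    chisq = c(per_term, global),
    df = c(rep(1L, p), p),
    p.value = pchisq(c(per_term, global), df = c(rep(1L, p), p),
                     lower.tail = FALSE))
  structure(list(table = table, transform = transform,
                 global_chisq = global, global_df = p,
                 global_p = table$p.value[p + 1]),
            class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat(sprintf("<ph_test> transform = %s\n", x$transform))
  print(x$table, ...)
  invisible(x)
}

#' @method tidy ph_test
#' @export
tidy.ph_test <- function(x, ...) x$table
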