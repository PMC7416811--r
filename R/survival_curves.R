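# product-limit estimator on raw vectors; censored subjects at an event time
# remain at risk at that time (standard convention)
km_compute <- function(times, events) {
  rc_assert(length(times) >= 1, "empty input")
  rc_assert(all(times > 0), "survival times must be strictly positive")
  rc_assert(all(events %in% c(0, 1)), "event indicator must be 0/1")
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  survival <- cumprod(1 - n_event / n_risk)
  tibble::tibble(time = ut, n_risk = as.integer(n_risk),
                 n_event = as.integer(n_event),
                 n_censor = as.integer(n_censor), survival = survival)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of the survival function, overall or per group.
#' Subjects censored at an event time are counted as still at risk at that
#' time.
#'
#' @param data Data frame with survival columns.
#' @param time,event,group Unquoted column names (defaults `time`, `event`;
#'   `group` optional).
#' @return A `km_curve` tibble with one row per distinct observed time (per
#'   group): `time`, `n_risk`, `n_event`, `n_censor` and the survival estimate
#'   `survival`. Rows with `n_censor > 0` mark the censoring ticks of the
#'   usual plot.
#' @examples
#' cohort <- generate_cohort(simulation_config(seed = 7))
#' kaplan_meier(cohort)
#' @export
kaplan_meier <- function(data, time = time, event = event, group = NULL) {
  times <- dplyr::pull(data, {{ time }})
  events <- dplyr::pull(data, {{ event }})
  g <- rlang::enquo(group)
  if (rlang::quo_is_null(g)) {
    out <- km_compute(times, events)
  } else {
    groups <- dplyr::pull(data, {{ group }})
    out <- dplyr::bind_rows(lapply(sort(unique(groups)), function(lev) {
      sel <- groups == lev
      dplyr::bind_cols(tibble::tibble(group = lev),
                       km_compute(times[sel], events[sel]))
    }))
  }
  class(out) <- c("km_curve", class(out))
  out
}

# G-sample log-rank on raw vectors
logrank_compute <- function(times, events, groups) {
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  G <- length(levs)
  rc_assert(G >= 2, "log-rank test needs at least 2 groups")
  event_times <- sort(unique(times[events == 1]))
  O <- setNames(numeric(G), levs)
  E <- setNames(numeric(G), levs)
  V <- matrix(0, G, G, dimnames = list(levs, levs))
  for (t in event_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    ng <- vapply(levs, function(l) sum(at_risk & groups == l), numeric(1))
    dg <- vapply(levs, function(l) sum(times == t & events == 1 & groups == l),
                 numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      # hypergeometric covariance of the per-group death counts at time t
      V <- V + d * (n - d) / (n - 1) *
        (diag(ng / n, G) - tcrossprod(ng / n))
    }
  }
  idx <- seq_len(G - 1)
  ome <- (O - E)[idx]
  chisq <- drop(t(ome) %*% solve(V[idx, idx, drop = FALSE]) %*% ome)
  list(chisq = chisq, df = G - 1L,
       p.value = pchisq(chisq, df = G - 1L, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Log-rank test of survival differences between groups
#'
#' Standard G-sample log-rank test: observed minus expected deaths accumulated
#' over the shared event times, with the hypergeometric covariance, referred to
#' a chi-square distribution with G-1 degrees of freedom.
#'
#' @inheritParams kaplan_meier
#' @param group Unquoted grouping column (required).
#' @return A one-row tibble: `statistic` (chi-square), `df`, `p.value`,
#'   `n_groups`.
#' @export
logrank_test <- function(data, time = time, event = event, group) {
  res <- logrank_compute(dplyr::pull(data, {{ time }}),
                         dplyr::pull(data, {{ event }}),
                         dplyr::pull(data, {{ group }}))
  tibble::tibble(statistic = res$chisq, df = res$df, p.value = res$p.value,
                 n_groups = res$df + 1L)
}

# median survival time from a km_compute() table: first time with S <= 0.5,
# Inf when the curve never reaches 0.5
km_median <- function(curve) {
  hit <- curve$time[curve$survival <= 0.5]
  if (length(hit) == 0) Inf else hit[1]
}
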