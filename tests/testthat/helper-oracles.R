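# Independent oracle implementations used to freeze expected values.
# These are written from the textbook definitions with naive loops, on
# purpose: they share no code with the package internals they check.

# log partial likelihood by direct risk-set enumeration (Efron or Breslow)
oracle_partial_loglik <- function(beta, time, event, x, ties = "efron") {
  ll <- 0
  for (tk in sort(unique(time[event == 1]))) {
    D <- which(time == tk & event == 1)
    R <- which(time >= tk)
    d <- length(D)
    ll <- ll + sum(beta * x[D])
    for (l in seq_len(d)) {
      f <- if (ties == "efron") (l - 1) / d else 0
      ll <- ll - log(sum(exp(beta * x[R])) - f * sum(exp(beta * x[D])))
    }
  }
  ll
}

# brute-force 1-covariate MLE: golden-section/optimize over a wide bracket
oracle_cox_mle <- function(time, event, x, ties = "efron") {
  stats::optimize(oracle_partial_loglik, c(-20, 20), maximum = TRUE,
                  time = time, event = event, x = x, ties = ties,
                  tol = 1e-10)$maximum
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  dev <- abs(u_obs - nx * ny / 2)
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(us - nx * ny / 2) >= dev - 1e-12)
}

# a small cohort with a single standard-normal biomarker and no confounder
# effects, for parameter-recovery style checks
single_biomarker_config <- function(n, beta, seed,
                                    censoring_rate = 0.3,
                                    n_subgroups = 1L) {
  simulation_config(
    n_patients = n, n_subgroups = n_subgroups, biomarker_names = "bm",
    subgroup_biomarker_means = matrix(0, n_subgroups, 1,
                                      dimnames = list(NULL, "bm")),
    hazard_coefficients = c(bm = beta),
    confounder_coefficients = list(age = 0, gender = c(male = 0),
                                   therapy = c(TACE = 0),
                                   diagnosis = c(CRC = 0, breast = 0,
                                                 other = 0)),
    censoring_rate = censoring_rate, seed = seed)
}

derive_seeds_for_test <- function(n, base = 1) base * 1000 + seq_len(n)

# random small survival datasets for oracle comparisons; skips degenerate
# draws (no events or boundary MLEs)
random_tiny_datasets <- function(n_datasets, max_n = 8, seed = 99) {
  set.seed(seed)
  out <- list()
  while (length(out) < n_datasets) {
    n <- sample(3:max_n, 1)
    d <- list(
      time = round(runif(n, 1, 20), 1),
      event = rbinom(n, 1, 0.8),
      x = if (runif(1) < 0.5) rbinom(n, 1, 0.5) else round(rnorm(n), 2))
    if (sum(d$event) == 0 || length(unique(d$x)) < 2) next
    mle <- oracle_cox_mle(d$time, d$event, d$x)
    if (abs(mle) > 5) next  # monotone-likelihood draws have no interior MLE
    d$mle <- mle
    out[[length(out) + 1]] <- d
  }
  out
}
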