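test_that("fit_cox matches brute-force partial-likelihood maximisation", {
  # the 4-patient toy with an exact closed-form partial likelihood
  toy <- tibble::tibble(time = c(1, 2, 3, 4), event = 1, x = c(1, 0, 1, 0))
  exact_ll <- function(b) {
    log(exp(b) / (2 * exp(b) + 2)) + log(1 / (exp(b) + 2)) +
      log(exp(b) / (exp(b) + 1))
  }
  b_grid <- stats::optimize(exact_ll, c(-20, 20), maximum = TRUE,
                            tol = 1e-10)$maximum
  fit <- fit_cox(toy, "x")
  expect_lt(abs(fit$beta[["x"]] - b_grid), 1e-6)
  expect_lt(abs(fit$loglik - exact_ll(fit$beta[["x"]])), 1e-10)
  # randomised tiny datasets against the independent definition-level oracle
  for (d in random_tiny_datasets(25)) {
    df <- tibble::tibble(time = d$time, event = d$event, x = d$x)
    fit <- fit_cox(df, "x")
    expect_lt(abs(fit$beta[["x"]] - d$mle), 1e-6)
  }
})

test_that("null log partial likelihood has the closed risk-set form", {
  set.seed(2)
  n <- 30
  df <- tibble::tibble(time = sample(seq_len(1000), n) / 10,  # no ties
                       event = rbinom(n, 1, 0.6),
                       x = rnorm(n))
  fit <- fit_cox(df, "x")
  expected <- -sum(vapply(df$time[df$event == 1],
                          function(t) log(sum(df$time >= t)), numeric(1)))
  expect_equal(fit$loglik_null, expected, tolerance = 1e-12)
})

test_that("Efron and Breslow agree when there are no ties", {
  set.seed(3)
  n <- 50
  df <- tibble::tibble(time = sample(seq_len(5000), n) / 10,
                       event = rbinom(n, 1, 0.7), x = rnorm(n),
                       z = rnorm(n))
  fe <- fit_cox(df, c("x", "z"), ties = "efron")
  fb <- fit_cox(df, c("x", "z"), ties = "breslow")
  expect_lt(max(abs(fe$beta - fb$beta)), 1e-10)
  expect_lt(abs(fe$loglik - fb$loglik), 1e-10)
})

test_that("the AIC identity holds on every fit", {
  cohort <- generate_cohort(simulation_config(seed = 12))
  for (terms in list("s100", c("s100", "age", "therapy"),
                     c("mmp9", "age", "gender", "therapy", "diagnosis",
                       "mmp9:therapy"))) {
    fit <- fit_cox(cohort, terms)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * length(fit$beta))
  }
})

test_that("fit_cox agrees with survival::coxph across tie settings", {
  skip_if_not_installed("survival")
  cohort <- generate_cohort(simulation_config(seed = 13))
  cohort$itime <- ceiling(cohort$time)  # force heavy ties
  for (ties in c("efron", "breslow")) {
    fit <- fit_cox(cohort, c("s100", "age", "gender", "therapy", "diagnosis"),
                   ties = ties, time_col = "itime")
    ref <- survival::coxph(
      survival::Surv(itime, event) ~ s100 + age + gender + therapy + diagnosis,
      data = cohort, ties = ties)
    expect_lt(max(abs(fit$beta - stats::coef(ref))), 1e-7)
    expect_lt(abs(fit$loglik - ref$loglik[2]), 1e-8)
    expect_lt(max(abs(fit$covariance - ref$var)), 1e-7)
  }
})

test_that("confounder terms enter each per-biomarker model", {
  cohort <- generate_cohort(simulation_config(seed = 14))
  for (bm in c("s100", "mmp9")) {
    fit <- fit_cox(cohort, c(bm, "age", "gender", "therapy", "diagnosis"))
    expect_true(all(c(bm, "age", "gender", "therapy", "diagnosis")
                    %in% fit$terms))
    # reference coding: first sorted level absorbed into the baseline
    expect_true("gendermale" %in% names(fit$beta))
    expect_false("genderfemale" %in% names(fit$beta))
  }
})

test_that("degenerate inputs raise informative errors", {
  df <- tibble::tibble(time = 1:4, event = 0, x = rnorm(4))
  expect_error(fit_cox(df, "x"), "no events")
  df$event <- 1
  df$y <- df$x  # collinear copy
  expect_error(fit_cox(df, c("x", "y")), "collinear")
  expect_error(fit_cox(df, "missing_col"), "missing_col")
})

test_that("linear predictors use the fit coding and are centred", {
  cohort <- generate_cohort(simulation_config(seed = 15))
  fit <- fit_cox(cohort, c("s100", "age", "therapy"))
  eta <- linear_predictor(fit, cohort)
  expect_lt(abs(mean(eta)), 1e-12)
  # beta = 0 vector gives a flat predictor
  fit0 <- fit
  fit0$beta[] <- 0
  expect_true(all(linear_predictor(fit0, cohort) == 0))
  # single standardised term with beta = 1 returns the centred column
  z <- tibble::tibble(time = cohort$time, event = cohort$event,
                      s = as.numeric(scale(cohort$s100)))
  fitz <- fit_cox(z, "s")
  fitz$beta[] <- 1
  expect_equal(linear_predictor(fitz, z), z$s - mean(z$s), tolerance = 1e-12)
})

test_that("tidy and glance summarise a fit", {
  cohort <- generate_cohort(simulation_config(seed = 16))
  fit <- fit_cox(cohort, c("s100", "age"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_true(all(td$p.value >= 0 & td$p.value <= 1))
  gl <- glance(fit)
  expect_equal(gl$n, 108)
  expect_true(gl$converged)
})
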