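test_that("generated cohort has the configured structure and is valid", {
  cfg <- simulation_config(seed = 11)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 108)
  expect_true(all(default_biomarkers() %in% names(cohort)))
  expect_true(all(c("patient_id", "time", "event", "age", "gender", "therapy",
                    "diagnosis", "comorbidities", "true_subgroup") %in%
                    names(cohort)))
  expect_true(all(cohort$time > 0))
  expect_true(all(cohort$event %in% 0:1))
  expect_false(anyDuplicated(cohort$patient_id) > 0)
  expect_false(anyNA(cohort))
  comet <- as.matrix(cohort[, c("comet_i", "comet_ii", "comet_iii", "comet_iv")])
  expect_true(all(comet >= 0))
  expect_lt(max(abs(rowSums(comet) - 1)), 1e-12)
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- simulation_config(seed = 5)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # a different seed changes the draw
  expect_false(identical(generate_cohort(cfg),
                         generate_cohort(simulation_config(seed = 6))))
})

test_that("config validation errors name the violated field", {
  expect_error(simulation_config(censoring_rate = 1.5), "censoring_rate")
  expect_error(simulation_config(baseline_shape = -1), "baseline_shape")
  expect_error(simulation_config(biomarker_noise_sd = 0), "biomarker_noise_sd")
  bad_means <- default_subgroup_means()[1:2, ]
  expect_error(simulation_config(subgroup_biomarker_means = bad_means),
               "subgroup_biomarker_means")
  # comet fractions must sum to one per subgroup
  m <- default_subgroup_means()
  m[1, "comet_i"] <- 0.9
  expect_error(simulation_config(subgroup_biomarker_means = m),
               "subgroup_biomarker_means")
})

test_that("zero hazard coefficients decouple biomarkers from survival", {
  cfg <- simulation_config(
    n_patients = 5000,
    hazard_coefficients = setNames(numeric(12), default_biomarkers()),
    seed = 21)
  cohort <- generate_cohort(cfg)
  p <- vapply(default_biomarkers(), function(bm) {
    stats::cor.test(cohort[[bm]], cohort$time, method = "kendall")$p.value
  }, numeric(1))
  expect_true(all(p > 0.01))
})

test_that("realised censoring tracks the configured rate", {
  cohort <- generate_cohort(simulation_config(n_patients = 5000, seed = 31))
  expect_lt(abs(mean(cohort$event == 0) - 0.3), 0.05)
})

test_that("no censoring means every death is observed", {
  cfg <- single_biomarker_config(200, beta = 0, seed = 41, censoring_rate = 0)
  cfg$admin_censor_time <- 1e9
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$event == 1))
})

test_that("unit-shape baseline reproduces the exponential mean", {
  # lp = 0, shape = 1, scale = 24: T ~ Exp(mean 24)
  cfg <- single_biomarker_config(20000, beta = 0, seed = 51, censoring_rate = 0)
  cfg$baseline_shape <- 1
  cfg$admin_censor_time <- 1e9
  set.seed(51)
  st <- generate_survival_times(rep(0, 20000), cfg)
  se <- 24 / sqrt(20000)
  expect_lt(abs(mean(st$time) - 24), 3 * se)
})

test_that("non-finite linear predictors are rejected", {
  cfg <- single_biomarker_config(10, beta = 0, seed = 1)
  expect_error(generate_survival_times(c(0, NA), cfg), "finite")
  expect_error(generate_survival_times(c(0, Inf), cfg), "finite")
})

test_that("Cox fits recover the planted hazard coefficient", {
  # beta = 0.7, n = 500: recovered within 3 SE in >= 90% of seeds
  hits <- vapply(derive_seeds_for_test(100, base = 7), function(s) {
    cohort <- generate_cohort(single_biomarker_config(500, beta = 0.7, seed = s))
    fit <- fit_cox(cohort, "bm")
    se <- sqrt(diag(fit$covariance))
    abs(fit$beta[["bm"]] - 0.7) <= 3 * se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a large planted log-hazard-ratio is recovered as a hazard ratio", {
  # two-point covariate with lp difference log(2) under shape 1: HR ~ 2
  cfg <- single_biomarker_config(4000, beta = log(2), seed = 61,
                                 censoring_rate = 0)
  cfg$baseline_shape <- 1
  cohort <- generate_cohort(cfg)
  fit <- fit_cox(cohort, "bm")
  expect_lt(abs(exp(fit$beta[["bm"]]) - 2), 0.15)
})
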