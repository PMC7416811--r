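test_that("chi-square matches the hand contingency formula", {
  tab <- matrix(c(20, 10, 10, 20), 2, 2, byrow = TRUE)
  res <- riskclust:::chisq_independence(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)  # sum (O-E)^2/E
  expect_equal(res$df, 1)
  # rows proportional to column margins: exactly zero
  prop <- matrix(c(10, 20, 20, 40), 2, 2, byrow = TRUE)
  expect_equal(riskclust:::chisq_independence(prop)$statistic, 0)
  expect_equal(riskclust:::chisq_independence(prop)$p.value, 1)
  # invariant under row/column permutation
  set.seed(70)
  t3 <- matrix(rpois(12, 20) + 5, 3, 4)
  base <- riskclust:::chisq_independence(t3)$statistic
  expect_equal(riskclust:::chisq_independence(t3[c(2, 3, 1), c(4, 1, 3, 2)])$statistic,
               base, tolerance = 1e-12)
})

test_that("confounder tests cover categorical and numeric confounders", {
  cohort <- generate_cohort(simulation_config(seed = 71))
  assignment <- cohort$true_subgroup
  res <- suppressWarnings(test_confounder_association(cohort, assignment))
  expect_setequal(res$confounder,
                  c("age", "gender", "therapy", "diagnosis", "comorbidities"))
  expect_equal(res$test[res$confounder == "age"], "anova_f")
  expect_true(all(res$p.value >= 0 & res$p.value <= 1))
  # identical ages across clusters give F = 0
  flat <- cohort
  flat$age <- 50
  res0 <- suppressWarnings(test_confounder_association(flat, assignment,
                                                       confounders = "age"))
  expect_equal(res0$statistic, 0)
  # single-level confounders are skipped with a warning
  flat$gender <- "female"
  expect_warning(
    test_confounder_association(flat, assignment, confounders = "gender"),
    "single level")
})

test_that("Wilcoxon p-values match exact enumeration", {
  res <- wilcoxon_rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1)   # 2 / choose(6, 3)
  expect_equal(res$statistic, 0)
  expect_equal(wilcoxon_rank_test(c(5, 9, 2), c(5, 9, 2))$p.value, 1)
  expect_warning(w <- wilcoxon_rank_test(c(3, 3), c(3, 3, 3)), "identical")
  expect_equal(w$p.value, 1)
  # exact branch vs the independent enumeration oracle, with and without ties
  set.seed(72)
  for (rep in 1:8) {
    nx <- sample(3:10, 1); ny <- sample(3:10, 1)
    x <- sample(seq_len(12), nx, replace = TRUE)  # ties likely
    y <- sample(seq_len(12), ny, replace = TRUE)
    if (diff(range(c(x, y))) == 0) next
    mine <- wilcoxon_rank_test(x, y, exact = TRUE)
    expect_equal(mine$p.value, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  }
})

test_that("the normal approximation stays close to exact enumeration", {
  set.seed(73)
  for (rep in 1:6) {
    nx <- sample(8:10, 1); ny <- sample(8:10, 1)
    x <- rnorm(nx); y <- rnorm(ny)  # continuous, no ties
    approx <- wilcoxon_rank_test(x, y, exact = FALSE)
    expect_equal(approx$method, "normal_approx")
    expect_lt(abs(approx$p.value - oracle_wilcoxon_exact(x, y)), 0.02)
  }
})

test_that("Benjamini-Hochberg follows the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(0.005, 0.04, 0.9)),
               c(0.015, 0.06, 0.9))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone, >= raw, matches stats::p.adjust, order-preserving
  set.seed(74)
  p <- runif(40)
  q <- benjamini_hochberg(p)
  expect_true(all(q >= p - 1e-15))
  expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("min-max normalisation maps columns into [0, 1]", {
  df <- tibble::tibble(a = c(2, 4, 6), b = c(1, 1, 1), c = rnorm(3))
  expect_warning(norm <- minmax_normalize(df, c("a", "b", "c")), "constant")
  expect_equal(norm$a, c(0, 0.5, 1))
  expect_equal(norm$b, c(0, 0, 0))
  expect_true(all(norm$c >= 0 & norm$c <= 1))
})

test_that("subgroup summaries compare the mask against the cohort", {
  df <- tibble::tibble(v = c(1, 2, 3, 4, 5))
  res <- subgroup_summary(df, c(FALSE, FALSE, FALSE, TRUE, TRUE), "v")
  expect_equal(res$subgroup_median, 4.5)
  expect_equal(res$cohort_median, 3)
  expect_equal(res$direction, "higher")
  all_in <- subgroup_summary(df, rep(TRUE, 5), "v")
  expect_equal(all_in$subgroup_median, all_in$cohort_median)
  expect_error(subgroup_summary(df, rep(FALSE, 5), "v"), "no patients")
  # joint diagnosis-by-therapy filtering on a cohort
  cohort <- generate_cohort(simulation_config(seed = 75))
  mask <- cohort$diagnosis == "HCC" & cohort$therapy == "TACE"
  res2 <- subgroup_summary(cohort, mask, c("mmp9", "s100"))
  expect_equal(nrow(res2), 2)
})

test_that("characterize assembles the full report with a joint BH family", {
  cohort <- generate_cohort(simulation_config(seed = 76))
  rep1 <- suppressWarnings(characterize(cohort, cohort$true_subgroup))
  expect_equal(nrow(rep1$biomarker_tests), 36)  # 3 cluster pairs x 12 markers
  expect_true(all(rep1$biomarker_tests$p.adjusted >=
                    rep1$biomarker_tests$p.value - 1e-15))
  expect_equal(rep1$bh_family, "global")
  # cluster labels ordered by median survival: 1 = worst, highest = best
  med <- rep1$cluster_survival$median_survival
  expect_equal(which.min(med), 1L)
  expect_true(med[1] <= min(med[-1]))
  # deterministic
  rep2 <- suppressWarnings(characterize(cohort, cohort$true_subgroup))
  expect_identical(rep1$biomarker_tests, rep2$biomarker_tests)
  expect_identical(rep1$logrank, rep2$logrank)
  gl <- glance(rep1)
  expect_equal(gl$n_clusters, 3L)
  expect_true(gl$logrank_p < 0.05)  # planted hazards separate the subgroups
})

test_that("shifted biomarkers reach BH significance between extreme clusters", {
  # the six planted prognostic markers should separate the worst from the best
  # cluster after BH in >= 90% of seeds
  signal <- c("s100", "profilin", "rhoa", "sod2", "thioredoxin", "mmp9")
  hits <- vapply(derive_seeds_for_test(20, base = 9), function(s) {
    cohort <- generate_cohort(simulation_config(seed = s))
    rep <- suppressWarnings(characterize(cohort, cohort$true_subgroup))
    extreme <- rep$biomarker_tests$cluster_a == 1 & rep$biomarker_tests$cluster_b == 3
    all(rep$biomarker_tests$p.adjusted[extreme &
          rep$biomarker_tests$biomarker %in% signal] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
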