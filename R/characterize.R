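#' Association of clusters with clinical confounders
#'
#' Pearson chi-square test (no continuity correction) on the cluster-by-
#' category contingency table for each categorical confounder, with a warning
#' when any expected count falls below 5; one-way ANOVA F-test for numeric
#' confounders (age). Confounders with a single observed level are skipped
#' with a warning.
#'
#' @param cohort Cohort data frame.
#' @param assignment Integer cluster labels, one per cohort row.
#' @param confounders Confounder column names.
#' @return Tibble: `confounder`, `test` (`"chi2"` or `"anova_f"`),
#'   `statistic`, `df1`, `df2` (`NA` for chi-square), `p.value`.
#' @export
test_confounder_association <- function(cohort, assignment,
                                        confounders = c("age", "gender",
                                                        "therapy", "diagnosis",
                                                        "comorbidities")) {
  rc_assert(length(assignment) == nrow(cohort),
            "assignment must cover the cohort")
  rc_assert(length(unique(assignment)) >= 2, "need at least 2 clusters")
  rows <- list()
  for (conf in confounders) {
    x <- cohort[[conf]]
    if (is.null(x)) {
      rlang::warn(sprintf("confounder `%s` not found; skipped", conf))
      next
    }
    if (is.numeric(x)) {
      res <- anova_f(x, assignment)
      rows[[conf]] <- tibble::tibble(confounder = conf, test = "anova_f",
                                     statistic = res$F, df1 = res$df1,
                                     df2 = res$df2, p.value = res$p.value)
    } else {
      if (length(unique(x)) < 2) {
        rlang::warn(sprintf("confounder `%s` has a single level; skipped", conf))
        next
      }
      res <- chisq_independence(table(assignment, x))
      rows[[conf]] <- tibble::tibble(confounder = conf, test = "chi2",
                                     statistic = res$statistic, df1 = res$df,
                                     df2 = NA_real_, p.value = res$p.value)
    }
  }
  dplyr::bind_rows(rows)
}

# Pearson chi-square on a contingency table, no Yates correction
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < 5)) {
    rlang::warn("chi-square test: some expected counts are below 5")
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}

anova_f <- function(x, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(x)
  grand <- mean(x)
  means <- tapply(x, groups, mean)
  ns <- tapply(x, groups, length)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((x - means[groups])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ss_between == 0) {
    # identical group means (possibly a constant variable): F = 0 by convention
    return(list(F = 0, df1 = df1, df2 = df2, p.value = 1))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, df1 = df1, df2 = df2,
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Reports the Mann-Whitney U statistic for `x`. When both groups have at
#' least 8 observations the normal approximation with mid-rank tie correction
#' and continuity correction is used; otherwise (or when `exact = TRUE`) the
#' exact permutation distribution of U is enumerated, and the two-sided p-value
#' is the probability of a deviation from `n_x n_y / 2` at least as large as
#' observed. If all pooled values are identical, `p = 1` with a warning.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` chooses by group size.
#' @return One-row tibble: `statistic` (U), `p.value`, `method`.
#' @export
wilcoxon_rank_test <- function(x, y, exact = NULL) {
  rc_assert(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  if (diff(range(pooled)) == 0) {
    rlang::warn("all pooled values identical; p = 1")
    return(tibble::tibble(statistic = nx * ny / 2, p.value = 1,
                          method = "degenerate"))
  }
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  use_exact <- exact %||% (min(nx, ny) < 8)
  if (use_exact) {
    dev <- abs(u - nx * ny / 2)
    combos <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - nx * ny / 2) >= dev - 1e-12)
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    cc <- min(0.5, abs(u - mu))  # continuity correction toward the mean
    z <- (u - mu - sign(u - mu) * cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  tibble::tibble(statistic = u, p.value = p, method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment \eqn{q_{(i)} = \min_{j \ge i} (m \, p_{(j)} / j)} over the
#' ascending ordering, capped at 1 and returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \eqn{[0,1]}.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  rc_assert(all(p_values >= 0 & p_values <= 1 & !is.na(p_values)),
            "p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric())
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Min-max normalisation of biomarker columns
#'
#' Rescales each biomarker column to \eqn{[0,1]} via \eqn{(x - \min) /
#' (\max - \min)}; a constant column maps to all zeros with a warning.
#'
#' @param cohort Data frame.
#' @param biomarkers Columns to normalise.
#' @return Tibble with the normalised biomarker columns (plus `patient_id`
#'   when present in `cohort`).
#' @export
minmax_normalize <- function(cohort, biomarkers) {
  out <- lapply(biomarkers, function(bm) {
    x <- cohort[[bm]]
    rc_assert(!is.null(x), sprintf("column `%s` not found", bm))
    rc_assert(sum(is.finite(x)) >= 1,
              sprintf("column `%s` has no finite values", bm))
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) {
      rlang::warn(sprintf("biomarker `%s` is constant; normalised to 0", bm))
      return(rep(0, length(x)))
    }
    (x - rng[1]) / diff(rng)
  })
  names(out) <- biomarkers
  out <- tibble::as_tibble(out)
  if ("patient_id" %in% names(cohort)) {
    out <- dplyr::bind_cols(tibble::tibble(patient_id = cohort$patient_id), out)
  }
  out
}

#' Median/IQR biomarker summary of a patient subgroup
#'
#' Compares a masked subgroup (e.g. one diagnosis-by-therapy stratum of a
#' cluster) against the full cohort: per-biomarker medians and interquartile
#' ranges for both, and the sign of the median difference.
#'
#' @param cohort Data frame.
#' @param mask Logical vector selecting the subgroup (>= 1 patient).
#' @param biomarkers Biomarker columns to summarise.
#' @return Tibble: `biomarker`, `subgroup_median`, `subgroup_iqr`,
#'   `cohort_median`, `cohort_iqr`, `direction` (`"higher"`, `"lower"`,
#'   `"equal"`).
#' @export
subgroup_summary <- function(cohort, mask, biomarkers) {
  rc_assert(length(mask) == nrow(cohort), "mask must cover the cohort")
  rc_assert(sum(mask) >= 1, "mask selects no patients")
  dplyr::bind_rows(lapply(biomarkers, function(bm) {
    x <- cohort[[bm]]
    sub <- x[mask]
    md_s <- median(sub); md_c <- median(x)
    tibble::tibble(
      biomarker = bm,
      subgroup_median = md_s, subgroup_iqr = stats::IQR(sub),
      cohort_median = md_c, cohort_iqr = stats::IQR(x),
      direction = dplyr::case_when(md_s > md_c ~ "higher",
                                   md_s < md_c ~ "lower",
                                   TRUE ~ "equal"))
  }))
}

# relabel clusters so that label 1 has the shortest median survival and the
# highest label the longest (the "cluster 3 = best survivors" convention)
order_clusters_by_survival <- function(time, event, assignment) {
  levs <- sort(unique(assignment))
  med <- vapply(levs, function(cl) {
    sel <- assignment == cl
    km_median(km_compute(time[sel], event[sel]))
  }, numeric(1))
  mean_t <- vapply(levs, function(cl) mean(time[assignment == cl]), numeric(1))
  new_order <- levs[order(med, mean_t)]
  map <- setNames(seq_along(levs), new_order)
  list(assignment = as.integer(map[as.character(assignment)]),
       map = map,
       median_survival = setNames(sort(med), seq_along(levs)))
}

#' Statistical characterisation of patient clusters
#'
#' Runs the full downstream analysis for a cluster assignment: clusters are
#' relabelled in increasing order of median survival (cluster 1 = worst,
#' highest label = best survivors); survival separation is tested by the
#' log-rank test; confounder associations by chi-square/ANOVA; every
#' cluster pair is compared on every biomarker by the two-sided Wilcoxon
#' rank-sum test with a single Benjamini-Hochberg correction applied jointly
#' across the whole family (or per biomarker with
#' `bh_family = "per_biomarker"`); biomarkers are min-max normalised and
#' summarised per cluster by median and IQR.
#'
#' @param cohort Cohort data frame (survival columns + confounders +
#'   biomarkers).
#' @param assignment Integer cluster labels, one per cohort row.
#' @param biomarkers Biomarker column names.
#' @param confounders Confounder columns for the association tests.
#' @param bh_family `"global"` (all pairs x all biomarkers, default) or
#'   `"per_biomarker"`.
#' @param fits Optional named list of `cox_fit`s to carry into the report.
#' @param time_col,event_col Survival column names.
#' @return A `characterization_report` with tibbles `logrank`,
#'   `confounder_tests`, `biomarker_tests` (raw and BH-adjusted p-values),
#'   `normalized_biomarkers`, `cluster_summaries`, `cluster_survival`, the
#'   relabelled `assignment`, and `bh_family`.
#' @export
characterize <- function(cohort, assignment,
                         biomarkers = default_biomarkers(),
                         confounders = c("age", "gender", "therapy",
                                         "diagnosis", "comorbidities"),
                         bh_family = c("global", "per_biomarker"),
                         fits = NULL,
                         time_col = "time", event_col = "event") {
  bh_family <- match.arg(bh_family)
  rc_assert(length(assignment) == nrow(cohort),
            "assignment must cover the cohort")
  time <- as.numeric(cohort[[time_col]])
  event <- as.integer(cohort[[event_col]])
  rel <- order_clusters_by_survival(time, event, assignment)
  assignment <- rel$assignment
  clusters <- sort(unique(assignment))
  lr <- logrank_compute(time, event, assignment)
  logrank <- tibble::tibble(statistic = lr$chisq, df = lr$df,
                            p.value = lr$p.value)
  conf_tests <- test_confounder_association(cohort, assignment,
                                            confounders = confounders)
  pairs <- utils::combn(clusters, 2, simplify = FALSE)
  bm_tests <- dplyr::bind_rows(lapply(biomarkers, function(bm) {
    dplyr::bind_rows(lapply(pairs, function(pr) {
      w <- wilcoxon_rank_test(cohort[[bm]][assignment == pr[1]],
                              cohort[[bm]][assignment == pr[2]])
      tibble::tibble(biomarker = bm, cluster_a = pr[1], cluster_b = pr[2],
                     statistic = w$statistic, p.value = w$p.value)
    }))
  }))
  if (bh_family == "global") {
    bm_tests$p.adjusted <- benjamini_hochberg(bm_tests$p.value)
  } else {
    bm_tests <- bm_tests |>
      dplyr::group_by(.data$biomarker) |>
      dplyr::mutate(p.adjusted = benjamini_hochberg(.data$p.value)) |>
      dplyr::ungroup()
  }
  normalized <- minmax_normalize(cohort, biomarkers)
  norm_mat <- normalized[, biomarkers, drop = FALSE]
  cluster_summaries <- dplyr::bind_rows(lapply(clusters, function(cl) {
    sel <- assignment == cl
    dplyr::bind_rows(lapply(biomarkers, function(bm) {
      tibble::tibble(cluster = cl, biomarker = bm,
                     median = median(norm_mat[[bm]][sel]),
                     iqr = stats::IQR(norm_mat[[bm]][sel]),
                     n = sum(sel))
    }))
  }))
  cluster_survival <- dplyr::bind_rows(lapply(clusters, function(cl) {
    sel <- assignment == cl
    tibble::tibble(cluster = cl, n = sum(sel), n_events = sum(event[sel]),
                   median_survival = km_median(km_compute(time[sel], event[sel])))
  }))
  structure(list(
    logrank = logrank, confounder_tests = conf_tests,
    biomarker_tests = bm_tests, normalized_biomarkers = normalized,
    cluster_summaries = cluster_summaries, cluster_survival = cluster_survival,
    assignment = assignment, bh_family = bh_family, fits = fits),
    class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat(sprintf("<characterization_report> %d clusters, BH family = %s\n",
              length(unique(x$assignment)), x$bh_family))
  cat(sprintf("log-rank: chi2 = %.3f, df = %d, p = %.3g\n",
              x$logrank$statistic, x$logrank$df, x$logrank$p.value))
  print(x$cluster_survival)
  sig <- x$biomarker_tests[x$biomarker_tests$p.adjusted < 0.05, ]
  cat(sprintf("%d of %d pairwise biomarker tests significant after BH (q < 0.05)\n",
              nrow(sig), nrow(x$biomarker_tests)))
  invisible(x)
}

#' @method tidy characterization_report
#' @export
tidy.characterization_report <- function(x, ...) x$biomarker_tests

#' @method glance characterization_report
#' @export
glance.characterization_report <- function(x, ...) {
  tibble::tibble(n_clusters = length(unique(x$assignment)),
                 logrank_chisq = x$logrank$statistic,
                 logrank_p = x$logrank$p.value,
                 n_biomarker_tests = nrow(x$biomarker_tests),
                 n_significant = sum(x$biomarker_tests$p.adjusted < 0.05),
                 bh_family = x$bh_family)
}
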