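# two well-separated Gaussian clouds in 2-D
two_cloud_profiles <- function(n_per = 15, gap = 50, seed = 50) {
  set.seed(seed)
  rbind(matrix(rnorm(2 * n_per, 0, 0.5), ncol = 2),
        matrix(rnorm(2 * n_per, gap, 0.5), ncol = 2))
}

test_that("planted partitions yield a 0/1 consensus matrix", {
  m <- two_cloud_profiles()
  res <- suppressWarnings(
    consensus_cluster(m, k_values = 2:3, n_resamples = 100, seed = 1))
  M <- res$consensus$k2
  within <- c(riskclust:::upper_tri_values(M[1:15, 1:15]),
              riskclust:::upper_tri_values(M[16:30, 16:30]))
  between <- as.vector(M[1:15, 16:30])
  expect_true(all(within == 1))
  expect_true(all(between == 0))
  expect_equal(unname(consensus_assignment(res, 2)[1:15]), rep(1L, 15))
})

test_that("full subsampling gives binary consensus entries", {
  m <- two_cloud_profiles(n_per = 10, gap = 8, seed = 51)
  res <- consensus_cluster(m, k_values = 2:4, n_resamples = 10,
                           subsample_fraction = 1, seed = 2)
  for (M in res$consensus) expect_true(all(M %in% c(0, 1)))
})

test_that("consensus matrices satisfy their structural invariants", {
  set.seed(52)
  m <- matrix(rnorm(35 * 4), ncol = 4)
  res <- consensus_cluster(m, k_values = 2:5, n_resamples = 40, seed = 3)
  for (M in res$consensus) {
    expect_equal(M, t(M))
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1))
  }
  for (k in 2:5) {
    a <- consensus_assignment(res, k)
    expect_setequal(unique(a), seq_len(k))  # exactly k non-empty clusters
  }
  expect_true(all(res$areas$A >= 0))
  # CDFs are non-decreasing from their floor to 1
  for (kk in unique(res$cdf$k)) {
    cdf <- res$cdf$cdf[res$cdf$k == kk]
    expect_true(all(diff(cdf) >= 0))
    expect_equal(cdf[length(cdf)], 1)
  }
})

test_that("permuting patients conjugates the consensus matrix (exact case)", {
  m <- two_cloud_profiles(n_per = 8, gap = 10, seed = 53)
  res <- consensus_cluster(m, k_values = 2:3, n_resamples = 5,
                           subsample_fraction = 1, seed = 4)
  perm <- sample(nrow(m))
  res_p <- consensus_cluster(m[perm, ], k_values = 2:3, n_resamples = 5,
                             subsample_fraction = 1, seed = 4)
  expect_equal(unname(res_p$consensus$k2), unname(res$consensus$k2[perm, perm]))
  expect_equal(res_p$areas, res$areas)
  expect_equal(res_p$selected_k, res$selected_k)
})

test_that("consensus clustering is deterministic given the seed", {
  set.seed(54)
  m <- matrix(rnorm(30 * 3), ncol = 3)
  r1 <- consensus_cluster(m, k_values = 2:4, n_resamples = 25, seed = 9)
  r2 <- consensus_cluster(m, k_values = 2:4, n_resamples = 25, seed = 9)
  expect_identical(r1, r2)
  r3 <- consensus_cluster(m, k_values = 2:4, n_resamples = 25, seed = 10)
  expect_false(identical(r1$consensus$k2, r3$consensus$k2))
})

test_that("the consensus CDF enumerates upper-triangle values", {
  n <- 4
  M0 <- diag(n); M0[upper.tri(M0)] <- 0; M0[lower.tri(M0)] <- 0; diag(M0) <- 1
  cdf0 <- consensus_cdf(M0)
  expect_true(all(cdf0$cdf == 1))  # jumps to 1 at 0
  M1 <- matrix(1, n, n)
  cdf1 <- consensus_cdf(M1)
  expect_true(all(cdf1$cdf[cdf1$consensus_value < 1] == 0))
  expect_equal(cdf1$cdf[101], 1)
  # entries {0, 0.5, 1} in equal numbers over the 6 pairs of a 4x4 matrix
  M <- matrix(0, n, n); diag(M) <- 1
  M[1, 2] <- M[2, 1] <- 0;   M[1, 3] <- M[3, 1] <- 0
  M[1, 4] <- M[4, 1] <- 0.5; M[2, 3] <- M[3, 2] <- 0.5
  M[2, 4] <- M[4, 2] <- 1;   M[3, 4] <- M[4, 3] <- 1
  cdf <- consensus_cdf(M)
  expect_equal(unique(cdf$cdf[cdf$consensus_value < 0.5]), 1 / 3)
  expect_equal(unique(cdf$cdf[cdf$consensus_value >= 0.5 &
                                cdf$consensus_value < 1]), 2 / 3)
  expect_equal(cdf$cdf[101], 1)
})

test_that("delta areas follow the stated recurrence", {
  res <- delta_area(c(0.4, 0.6, 0.63, 0.64), k_values = 2:5)
  expect_equal(res$delta, c(0.4, 0.5, 0.05, 0.0159), tolerance = 5e-3)
  expect_equal(res$delta[4], (0.64 - 0.63) / 0.63, tolerance = 1e-12)
  # identical CDFs give zero gains beyond k = 2
  flat <- delta_area(c(0.5, 0.5, 0.5), k_values = 2:4)
  expect_equal(flat$delta, c(0.5, 0, 0))
  expect_error(delta_area(0.4), "at least two")
})

test_that("select_k applies the delta-area rule with parsimony tie-break", {
  expect_equal(select_k(setNames(c(0.4, 0.5, 0.05, 0.0159), 2:5)), 3L)
  expect_equal(select_k(setNames(c(0.4, 0.02, 0.03, 0.01), 2:5)), 2L)
  expect_equal(select_k(setNames(c(0.4, 0.3, 0.3, 0.1), 2:5)), 3L)  # tie -> 3
  # a k >= 3 gain below tau falls back to 2
  expect_equal(select_k(setNames(c(0.9, 0.09, 0.01, 0.0), 2:5)), 2L)
})

test_that("stability metrics average the right consensus entries", {
  M <- matrix(0.1, 4, 4); diag(M) <- 1
  M[1, 2] <- M[2, 1] <- 0.8
  M[3, 4] <- M[4, 3] <- 0.6
  sm <- stability_metrics(M, c(1, 1, 2, 2))
  expect_equal(sm$cluster_consensus$consensus, c(0.8, 0.6))
  ic <- sm$item_consensus
  expect_equal(ic$consensus[ic$item == 1 & ic$cluster == 2], 0.1)
  expect_equal(ic$consensus[ic$item == 1 & ic$cluster == 1], 0.8)
  # perfect block matrix: own-cluster consensus 1, other-cluster 0
  B <- matrix(0, 4, 4); B[1:2, 1:2] <- 1; B[3:4, 3:4] <- 1
  smb <- stability_metrics(B, c(1, 1, 2, 2))
  expect_equal(smb$cluster_consensus$consensus, c(1, 1))
  icb <- smb$item_consensus
  expect_true(all(icb$consensus[(icb$item <= 2) == (icb$cluster == 1)] == 1))
  expect_true(all(icb$consensus[(icb$item <= 2) != (icb$cluster == 1)] == 0))
  # singleton clusters are flagged
  expect_warning(stability_metrics(M, c(1, 1, 2, 3)), "singleton")
})

test_that("rarely co-sampled pairs are reported", {
  set.seed(55)
  m <- matrix(rnorm(20 * 2), ncol = 2)
  expect_warning(
    res <- consensus_cluster(m, k_values = 2:3, n_resamples = 2,
                             subsample_fraction = 0.4, seed = 6),
    "never co-sampled")
  expect_false(res$valid)
})
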