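profile_matrix <- function(profiles) {
  if (inherits(profiles, "risk_profile_matrix")) {
    m <- as.matrix(profiles$profiles[, profiles$biomarkers, drop = FALSE])
    rownames(m) <- profiles$profiles$patient_id
    return(m)
  }
  if (is.data.frame(profiles)) {
    ids <- NULL
    if ("patient_id" %in% names(profiles)) {
      ids <- profiles$patient_id
      profiles <- profiles[, setdiff(names(profiles), "patient_id"),
                           drop = FALSE]
    }
    m <- as.matrix(profiles)
    if (!is.null(ids)) rownames(m) <- ids
    return(m)
  }
  as.matrix(profiles)
}

profile_distance <- function(m, distance) {
  switch(distance,
    euclidean = as.matrix(stats::dist(m)),
    pearson = {
      d <- 1 - stats::cor(t(m))
      diag(d) <- 0
      d
    })
}

#' Consensus hierarchical clustering of patient risk profiles
#'
#' Resampling-based consensus clustering: for each of `n_resamples` resamples a
#' random subset of `subsample_fraction * n` patients is drawn without
#' replacement and clustered hierarchically for every `k` in `k_values`. The
#' consensus matrix entry \eqn{M_k(i,j)} is the fraction of resamples
#' containing both patients in which they were assigned to the same cluster.
#' For each `k` the final assignment is a hierarchical clustering of
#' `1 - M_k` cut at `k`; the consensus CDF, its area \eqn{A(k)}, the relative
#' area increase \eqn{\Delta(k)}, the selected number of clusters, and the
#' cluster/item consensus stability metrics are all returned. Deterministic
#' given `seed`.
#'
#' @param profiles A `risk_profile_matrix` (see [build_risk_profiles()]), data
#'   frame (optional `patient_id` column) or numeric matrix, patients in rows.
#' @param k_values Consecutive ascending cluster numbers starting at 2.
#' @param n_resamples Number of resampling repeats (>= 2).
#' @param subsample_fraction Fraction of patients drawn per resample, in
#'   (0, 1].
#' @param linkage Linkage for [hierarchical_cluster()].
#' @param distance `"euclidean"` or `"pearson"` (correlation distance).
#' @param tau Delta-area floor for preferring some `k >= 3` over `k = 2`
#'   (see [select_k()]).
#' @param seed Integer seed.
#' @return A `consensus_result`: `consensus` (named list of n-by-n matrices),
#'   `assignments` (tibble `patient_id`, one `k<k>` column per k), `cdf`
#'   (tibble), `areas` (tibble with `A` and `delta`), `selected_k`,
#'   `cluster_consensus`, `item_consensus`, `params`.
#' @export
consensus_cluster <- function(profiles, k_values = 2:5, n_resamples = 100,
                              subsample_fraction = 0.8,
                              linkage = "average",
                              distance = c("euclidean", "pearson"),
                              tau = 0.1, seed = 1L) {
  distance <- match.arg(distance)
  m <- profile_matrix(profiles)
  n <- nrow(m)
  ids <- rownames(m) %||% as.character(seq_len(n))
  rc_assert(n_resamples >= 2, "n_resamples must be at least 2")
  rc_assert(subsample_fraction > 0 && subsample_fraction <= 1,
            "subsample_fraction must lie in (0, 1]")
  rc_assert(all(diff(k_values) == 1) && k_values[1] == 2,
            "k_values must be consecutive ascending and start at 2")
  m_sub <- ceiling(subsample_fraction * n)
  rc_assert(max(k_values) < m_sub || (subsample_fraction == 1 && max(k_values) <= n),
            "max(k_values) must be smaller than the subsample size")
  set.seed(as.integer(seed))
  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(k_values, function(k) matrix(0, n, n))
  names(co_clustered) <- paste0("k", k_values)
  full_d <- profile_distance(m, distance)
  for (r in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, m_sub))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    agg <- agglomerate(full_d[idx, idx], linkage)
    for (ki in seq_along(k_values)) {
      lab <- cut_agglomeration(agg, k_values[ki])
      for (cl in unique(lab)) {
        mem <- idx[lab == cl]
        co_clustered[[ki]][mem, mem] <- co_clustered[[ki]][mem, mem] + 1
      }
    }
  }
  never <- co_sampled == 0 & upper.tri(co_sampled)
  n_never <- sum(never)
  if (n_never > 0) {
    rlang::warn(sprintf(
      "%d patient pair(s) were never co-sampled; their consensus is set to 0",
      n_never))
  }
  valid <- n_never <= 0.01 * n * (n - 1) / 2
  denom <- co_sampled
  denom[denom == 0] <- 1
  consensus <- lapply(co_clustered, function(cc) {
    M <- cc / denom
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    M
  })
  assignments <- tibble::tibble(patient_id = ids)
  cdf_tbl <- list(); area <- numeric(length(k_values))
  cluster_cons <- list(); item_cons <- list()
  for (ki in seq_along(k_values)) {
    k <- k_values[ki]
    M <- consensus[[ki]]
    d_cons <- 1 - M
    diag(d_cons) <- 0
    assignments[[paste0("k", k)]] <- hierarchical_cluster(d_cons, linkage, k)
    cdf <- consensus_cdf(M)
    cdf_tbl[[ki]] <- dplyr::bind_cols(tibble::tibble(k = k), cdf)
    area[ki] <- trapezoid(cdf$consensus_value, cdf$cdf)
    sm <- stability_metrics(M, assignments[[paste0("k", k)]])
    cluster_cons[[ki]] <- dplyr::bind_cols(tibble::tibble(k = k),
                                           sm$cluster_consensus)
    item_cons[[ki]] <- dplyr::bind_cols(tibble::tibble(k = k),
                                        sm$item_consensus)
  }
  delta <- delta_area_from_areas(area)
  areas <- tibble::tibble(k = k_values, A = area, delta = delta)
  selected <- select_k(setNames(delta, k_values), tau = tau)
  structure(list(
    k_values = k_values, consensus = consensus, assignments = assignments,
    cdf = dplyr::bind_rows(cdf_tbl), areas = areas, selected_k = selected,
    cluster_consensus = dplyr::bind_rows(cluster_cons),
    item_consensus = dplyr::bind_rows(item_cons),
    n_never_cosampled = n_never, valid = valid,
    params = list(n_resamples = n_resamples,
                  subsample_fraction = subsample_fraction,
                  linkage = linkage, distance = distance, tau = tau,
                  seed = as.integer(seed))),
    class = "consensus_result")
}

#' Empirical CDF of a consensus matrix
#'
#' Empirical cumulative distribution of the \eqn{n(n-1)/2} upper-triangular
#' consensus values, evaluated on the fixed grid \eqn{0, 0.01, \ldots, 1}
#' (101 points) so that areas are reproducible bit-for-bit.
#'
#' @param consensus_matrix Symmetric matrix with unit diagonal, entries in
#'   \eqn{[0,1]}.
#' @return Tibble with columns `consensus_value` (the grid) and `cdf`.
#' @export
consensus_cdf <- function(consensus_matrix) {
  M <- as.matrix(consensus_matrix)
  rc_assert(nrow(M) >= 2, "consensus matrix must cover at least 2 items")
  vals <- upper_tri_values(M)
  rc_assert(all(vals >= 0 & vals <= 1), "consensus values must lie in [0, 1]")
  grid <- seq(0, 1, by = 0.01)
  tibble::tibble(consensus_value = grid,
                 cdf = vapply(grid, function(g) mean(vals <= g), numeric(1)))
}

delta_area_from_areas <- function(area) {
  delta <- numeric(length(area))
  delta[1] <- area[1]
  if (length(area) > 1) {
    delta[-1] <- diff(area) / utils::head(area, -1)
  }
  delta
}

#' Relative change of the area under the consensus CDF
#'
#' Given consensus CDFs for consecutive `k = 2, 3, ...`, computes the
#' trapezoidal area \eqn{A(k)} under each CDF and the delta areas
#' \eqn{\Delta(2) = A(2)}, \eqn{\Delta(k) = (A(k) - A(k-1)) / A(k-1)} for
#' `k > 2`.
#'
#' @param cdfs Either a list of CDF tibbles (as returned by
#'   [consensus_cdf()]) ordered by k starting at 2, or a numeric vector of
#'   areas `A(k)`.
#' @param k_values The k each entry belongs to.
#' @return Tibble with columns `k`, `A`, `delta`.
#' @export
delta_area <- function(cdfs, k_values = seq(2, length.out = length(cdfs))) {
  rc_assert(length(cdfs) >= 2, "delta_area needs at least two k values")
  rc_assert(k_values[1] == 2 && all(diff(k_values) == 1),
            "k values must be consecutive ascending, starting at 2")
  area <- if (is.numeric(cdfs)) {
    as.numeric(cdfs)
  } else {
    vapply(cdfs, function(cdf) trapezoid(cdf$consensus_value, cdf$cdf),
           numeric(1))
  }
  tibble::tibble(k = k_values, A = area, delta = delta_area_from_areas(area))
}

#' Select the number of clusters by the delta-area rule
#'
#' Picks the `k >= 3` maximising \eqn{\Delta(k)} provided that maximum exceeds
#' the floor `tau` (default 0.1); otherwise 2. Ties go to the smaller `k`
#' (parsimony).
#'
#' @param delta_areas Named numeric vector of \eqn{\Delta(k)} (names = k), or
#'   the tibble returned by [delta_area()].
#' @param tau Minimum relative area gain required to move beyond `k = 2`.
#' @return The selected k (integer).
#' @export
select_k <- function(delta_areas, tau = 0.1) {
  if (is.data.frame(delta_areas)) {
    delta_areas <- setNames(delta_areas$delta, delta_areas$k)
  }
  ks <- as.integer(names(delta_areas))
  rc_assert(!any(is.na(ks)), "delta_areas must be named by k")
  cand <- ks >= 3
  if (!any(cand)) return(2L)
  d <- delta_areas[cand]
  best <- which(d == max(d))[1]  # smallest k on ties
  if (d[best] > tau) ks[cand][best] else 2L
}

#' Cluster and item consensus stability metrics
#'
#' Cluster consensus: mean consensus over distinct within-cluster pairs
#' (undefined, reported `NA` with a warning, for singletons). Item consensus of
#' patient i with cluster c: mean consensus of i with the members of c
#' (excluding i itself when i belongs to c).
#'
#' @param consensus_matrix Consensus matrix.
#' @param assignment Integer cluster labels covering the matrix's items.
#' @return List with tibbles `cluster_consensus` (`cluster`, `size`,
#'   `consensus`) and `item_consensus` (`item`, `cluster`, `consensus`).
#' @export
stability_metrics <- function(consensus_matrix, assignment) {
  M <- as.matrix(consensus_matrix)
  n <- nrow(M)
  rc_assert(length(assignment) == n,
            "assignment must cover all items of the consensus matrix")
  clusters <- sort(unique(assignment))
  cc <- vapply(clusters, function(cl) {
    mem <- which(assignment == cl)
    if (length(mem) < 2) {
      rlang::warn(sprintf("cluster %s is a singleton; cluster consensus undefined", cl))
      return(NA_real_)
    }
    mean(upper_tri_values(M[mem, mem, drop = FALSE]))
  }, numeric(1))
  ic <- tidyr::expand_grid(item = seq_len(n), cluster = clusters)
  ic$consensus <- mapply(function(i, cl) {
    mem <- setdiff(which(assignment == cl), i)
    if (length(mem) == 0) return(NA_real_)
    mean(M[i, mem])
  }, ic$item, ic$cluster)
  list(
    cluster_consensus = tibble::tibble(
      cluster = clusters,
      size = vapply(clusters, function(cl) sum(assignment == cl), integer(1)),
      consensus = cc),
    item_consensus = ic)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> n = %d patients, k in {%s}, %d resamples (fraction %.2f)\n",
              nrow(x$assignments), paste(x$k_values, collapse = ", "),
              x$params$n_resamples, x$params$subsample_fraction))
  print(x$areas)
  cat(sprintf("selected k = %d (delta-area rule, tau = %.2f)\n",
              x$selected_k, x$params$tau))
  invisible(x)
}

#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) x$areas

#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(n = nrow(x$assignments), selected_k = x$selected_k,
                 n_resamples = x$params$n_resamples,
                 subsample_fraction = x$params$subsample_fraction,
                 linkage = x$params$linkage, distance = x$params$distance,
                 valid = x$valid)
}

#' Cluster assignment at a given k
#'
#' @param result A `consensus_result`.
#' @param k Number of clusters (default: the selected k).
#' @return Named integer vector of cluster labels (names = patient ids).
#' @export
consensus_assignment <- function(result, k = result$selected_k) {
  col <- paste0("k", k)
  rc_assert(col %in% names(result$assignments), "k was not clustered")
  setNames(result$assignments[[col]], result$assignments$patient_id)
}
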