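# Agglomerative clustering via Lance-Williams updates. Returns the merge
# sequence (pairs of cluster representatives = smallest original member index)
# and merge heights. Ties are broken deterministically by the lexicographically
# smallest index pair.
agglomerate <- function(d, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  D <- as_distance_matrix(d)
  n <- nrow(D)
  if (n == 1) return(list(merges = list(), heights = numeric(), n = 1L))
  if (linkage == "ward") D <- D^2  # ward.D2 on squared distances
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  work <- D
  diag(work) <- Inf
  work[lower.tri(work)] <- Inf
  merges <- vector("list", n - 1)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- min(work)
    cand <- which(work == m, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]  # i < j by upper-tri storage
    merges[[step]] <- c(i, j)
    heights[step] <- if (linkage == "ward") sqrt(m) else m
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    for (o in others) {
      dio <- D[i, o]; djo <- D[j, o]
      new <- switch(linkage,
        average = (size[i] * dio + size[j] * djo) / (size[i] + size[j]),
        complete = max(dio, djo),
        ward = ((size[i] + size[o]) * dio + (size[j] + size[o]) * djo -
                  size[o] * D[i, j]) / (size[i] + size[j] + size[o]))
      D[i, o] <- new; D[o, i] <- new
      work[min(i, o), max(i, o)] <- new
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    work[j, ] <- Inf; work[, j] <- Inf
  }
  list(merges = merges, heights = heights, n = n)
}

# cut an agglomeration at k clusters; labels 1..k in order of first appearance
cut_agglomeration <- function(agg, k) {
  n <- agg$n
  rc_assert(k >= 1 && k <= n, "k must lie in 1..n")
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  n_merge <- n - k
  for (step in seq_len(n_merge)) {
    pair <- agg$merges[[step]]
    parent[find(pair[2])] <- find(pair[1])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard agglomerative clustering with average (UPGMA, default), complete or
#' Ward (ward.D2) linkage and a deterministic tie-break (the pair with the
#' lexicographically smallest indices is merged first), cut into `k` groups.
#'
#' @param d Symmetric distance matrix (or `dist`) with zero diagonal.
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels `1..k` (numbered in order of first
#'   appearance).
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete", "ward"),
                                 k) {
  agg <- agglomerate(d, linkage)
  cut_agglomeration(agg, k)
}
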