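#' @importFrom rlang %||% abort warn .data
#' @importFrom stats pchisq pnorm median quantile rnorm runif rgamma rexp
#' @importFrom stats complete.cases setNames var sd
NULL

# internal: stop with a classed riskclust error
rc_abort <- function(msg, class = "riskclust_error", ...) {
  rlang::abort(msg, class = c(class, "riskclust_error"), ...)
}

rc_assert <- function(cond, msg, class = "riskclust_error") {
  if (!isTRUE(cond)) rc_abort(msg, class = class)
}

# trapezoidal area under y(x) on an ascending grid
trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# adjusted Rand index between two hard partitions (Hubert & Arabie)
adjusted_rand_index <- function(a, b) {
  rc_assert(length(a) == length(b), "partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# coerce dist / matrix input to a validated symmetric distance matrix
as_distance_matrix <- function(d, arg = "d") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  rc_assert(nrow(d) == ncol(d), sprintf("`%s` must be square", arg))
  rc_assert(max(abs(d - t(d))) < 1e-8, sprintf("`%s` must be symmetric", arg))
  rc_assert(all(abs(diag(d)) < 1e-12), sprintf("`%s` must have a zero diagonal", arg))
  rc_assert(all(d >= -1e-12), sprintf("`%s` must be non-negative", arg))
  d
}

upper_tri_values <- function(m) m[upper.tri(m)]

# deterministic per-replicate seeds derived from a master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 100000L) * 10000L + seq_len(n)
}
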