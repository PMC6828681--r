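# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, in the sorted order.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Right-tail hypergeometric p by exhaustive enumeration of all list-sized
# subsets of the universe (feasible for universes <= 15).
brute_hyper <- function(universe_size, set_size, list_size, overlap) {
  subsets <- utils::combn(universe_size, list_size)
  in_set <- seq_len(set_size)  # wlog the set is the first set_size elements
  hits <- apply(subsets, 2, function(s) sum(s %in% in_set))
  mean(hits >= overlap)
}

# Topological overlap by triple loop.
brute_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# NB-conditional two-sided p via stats::dnbinom products (the mean cancels in
# the conditional, so any mu > 0 works); probability-mass ordering.
brute_nb_conditional <- function(sa, sb, na, nb, phi) {
  n <- sa + sb
  x <- 0:n
  w <- stats::dnbinom(x, size = na / phi, mu = 7) *
       stats::dnbinom(n - x, size = nb / phi, mu = 7)
  pr <- w / sum(w)
  sum(pr[pr <= pr[sa + 1] * (1 + 1e-9)])
}

# TMM factor for sample i vs reference r, from the written rule: doubly
# trimmed precision-weighted mean of log2 ratios over co-expressed genes.
brute_tmm_pair <- function(yi, yr, trim_m = 0.3, trim_a = 0.05) {
  ni <- sum(yi); nr <- sum(yr)
  ok <- yi > 0 & yr > 0
  m <- log2((yi[ok] / ni) / (yr[ok] / nr))
  a <- 0.5 * log2((yi[ok] / ni) * (yr[ok] / nr))
  w <- 1 / ((ni - yi[ok]) / (ni * yi[ok]) + (nr - yr[ok]) / (nr * yr[ok]))
  n <- length(m)
  keep_m <- rank(m, ties.method = "first")
  keep_a <- rank(a, ties.method = "first")
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- keep_m >= lo_m & keep_m <= hi_m & keep_a >= lo_a & keep_a <= hi_a
  2^(sum(w[keep] * m[keep]) / sum(w[keep]))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
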