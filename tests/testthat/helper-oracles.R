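# Independent brute-force implementations of the graph metrics, used as
# oracles against the package's vectorized versions. Deliberately naive:
# explicit loops and enumeration only.

oracle_density <- function(a) {
  n <- nrow(a)
  edges <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) edges <- edges + a[i, j]
  edges / (n * (n - 1) / 2)
}

# triangles and connected triples by enumerating every unordered triple
oracle_clustering <- function(a) {
  n <- nrow(a)
  n_tri <- 0L
  n_triple <- 0L
  for (combo in utils::combn(n, 3, simplify = FALSE)) {
    i <- combo[1]; j <- combo[2]; k <- combo[3]
    e <- a[i, j] + a[i, k] + a[j, k]
    if (e == 3) {
      n_tri <- n_tri + 1L
      n_triple <- n_triple + 3L       # each vertex is the center of a path
    } else if (e == 2) {
      n_triple <- n_triple + 1L
    }
  }
  if (n_triple == 0) return(0)
  3 * n_tri / n_triple
}

# Floyd-Warshall all-pairs shortest paths
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_efficiency <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.finite(d[i, j]) && d[i, j] > 0) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1) / 2)
}

# connected components from the distance matrix; centrality by dense
# eigendecomposition of the largest component (first one of maximal size)
oracle_centrality <- function(a) {
  n <- nrow(a)
  if (sum(a) == 0) return(rep(0, n))
  d <- oracle_distances(a)
  membership <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0) {
      comp <- comp + 1L
      membership[is.finite(d[i, ])] <- comp
    }
  }
  sizes <- tabulate(membership)
  keep <- membership == which.max(sizes)
  sub <- a[keep, keep, drop = FALSE]
  v <- eigen(sub, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)                       # Perron vector is sign-ambiguous
  out <- rep(0, n)
  out[keep] <- v / max(v)
  out
}

# random symmetric hollow adjacency matrix
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  ut <- upper.tri(a)
  a[ut] <- stats::rbinom(sum(ut), 1, p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# named graphs used across tests
star_graph <- function(n) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1L
  a
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

cycle_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a[i, j] <- a[j, i] <- 1L
  }
  a
}

# small cohort configuration that keeps property tests fast
small_config <- function(...) {
  cohort_config(n_bins = 30, m_control = 10, m_disease = 10,
                hub_bins = c(5, 15), partners_per_hub = 5, ...)
}
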