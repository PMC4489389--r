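# Independent brute-force oracles. These deliberately avoid the package's
# BFS/C++ code paths: distances come from Floyd-Warshall, clustering from
# direct neighbour-pair enumeration, Pearson r and the trapezoid rule from
# their textbook definitions.

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    through_k <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, through_k)
  }
  d
}

oracle_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  cl <- numeric(n)
  eloc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k >= 2) {
      sub <- adj[nb, nb, drop = FALSE]
      t_edges <- sum(sub) / 2
      cl[i] <- t_edges / (k * (k - 1) / 2)
      dsub <- oracle_fw_distances(sub)
      inv <- 1 / dsub
      diag(inv) <- 0
      inv[!is.finite(inv)] <- 0
      eloc[i] <- sum(inv) / (k * (k - 1))
    }
  }
  d <- oracle_fw_distances(adj)
  ut <- d[upper.tri(d)]
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  list(cp = mean(cl), clustering = cl,
       lp = if (any(is.finite(ut))) mean(ut[is.finite(ut)]) else Inf,
       n_unreachable_pairs = sum(!is.finite(ut)),
       eglob = sum(inv) / (n * (n - 1)),
       eloc = mean(eloc), nodal_eloc = eloc,
       distances = d)
}

oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i + 1] + y[i]) / 2
  s
}

# Erdos-Renyi adjacency via the current RNG
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# adjacency from an explicit edge list (2-column matrix of node indices)
adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (r in seq_len(nrow(edges))) {
    a[edges[r, 1], edges[r, 2]] <- 1L
    a[edges[r, 2], edges[r, 1]] <- 1L
  }
  a
}

make_net <- function(adj, sparsity = NA_real_) {
  binary_network(adj, sparsity = sparsity)
}

# small, fast cohort settings for generator property tests
quick_spec <- function(seed, ...) {
  args <- list(n_patients = 6, n_controls = 6, n_regions = 30,
               n_timepoints = 120, n_modules = 3, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# a connectivity matrix with prescribed upper-triangle values
cm_from_upper <- function(vals, n, subject_id = "fix") {
  r <- matrix(0, n, n)
  r[upper.tri(r)] <- vals
  r <- r + t(r)
  connectivity_matrix(r, subject_id = subject_id)
}
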