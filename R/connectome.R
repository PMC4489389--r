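#' Pearson correlation connectome
#'
#' Correlates every pair of regional time series. The diagonal is stored as
#' zero (self-connections are never edges).
#'
#' @param ts a [time_series_matrix()].
#' @return a [connectivity_matrix()].
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "time_series_matrix"))
  v <- apply(ts$data, 1, var)
  if (any(v == 0))
    stop_fcnet("degenerate (zero-variance) signal in region(s): %s",
               paste(ts$region_ids[v == 0], collapse = ", "))
  r <- cor(t(ts$data))
  diag(r) <- 0
  connectivity_matrix(r, subject_id = ts$subject_id,
                      region_ids = ts$region_ids)
}

#' Sparsity grid
#'
#' The ordered set of network densities at which binary networks are built.
#' The default grid 0.05, 0.06, ..., 0.40 has 36 values.
#'
#' @param s_min,s_max grid endpoints, `0 < s_min <= s_max < 1`; a degenerate
#'   single-threshold grid (`s_min == s_max`) is allowed.
#' @param step increment; `s_max` must lie on the grid.
#' @return an object of class `sparsity_grid` with element `values`.
#' @export
sparsity_grid <- function(s_min = 0.05, s_max = 0.40, step = 0.01) {
  if (!(s_min > 0 && s_min <= s_max && s_max < 1))
    stop_fcnet("need 0 < s_min <= s_max < 1 (got %g, %g)", s_min, s_max)
  if (step <= 0) stop_fcnet("step must be positive")
  n_steps <- round((s_max - s_min) / step)
  if (abs(s_min + n_steps * step - s_max) > 1e-8)
    stop_fcnet("s_max (%g) does not lie on the grid s_min + k*step", s_max)
  values <- round(s_min + step * (0:n_steps), 10)
  structure(list(s_min = s_min, s_max = s_max, step = step, values = values),
            class = "sparsity_grid")
}

#' @export
print.sparsity_grid <- function(x, ...) {
  cat(sprintf("<sparsity_grid> %g to %g by %g (%d values)\n",
              x$s_min, x$s_max, x$step, length(x$values)))
  invisible(x)
}

#' Sparsity thresholding of a connectivity matrix
#'
#' Keeps the `K = round(S * N(N-1)/2)` strongest connections as edges
#' (round-half-away-from-zero, so realized density is as close as possible
#' to nominal). By default only positive correlations are candidate edges,
#' the dominant convention for binary resting-state networks; set
#' `edge_sign = "absolute"` to rank by `|r|`. Ties at the K-th value are
#' broken by ascending lexicographic node-pair order, so edge sets are fully
#' deterministic.
#'
#' @param cm a [connectivity_matrix()].
#' @param sparsity target density in (0, 1).
#' @param edge_sign `"positive"` (default) or `"absolute"`.
#' @return a [binary_network()].
#' @export
threshold_by_sparsity <- function(cm, sparsity,
                                  edge_sign = c("positive", "absolute")) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  edge_sign <- match.arg(edge_sign)
  if (!(sparsity > 0 && sparsity < 1))
    stop_fcnet("sparsity must lie in (0, 1), got %g", sparsity)
  n <- nrow(cm$r)
  m <- n * (n - 1) / 2
  k <- as.integer(round_half_away(sparsity * m))
  ut <- which(upper.tri(cm$r), arr.ind = TRUE)
  score <- cm$r[ut]
  if (edge_sign == "absolute") score <- abs(score)
  cand <- which(score > 0)
  if (length(cand) < k)
    stop_fcnet(paste0("only %d positive connections for %d requested edges; ",
                      "maximum achievable sparsity is %.4f"),
               length(cand), k, length(cand) / m)
  ord <- cand[order(-score[cand], ut[cand, 1], ut[cand, 2])]
  keep <- ord[seq_len(k)]
  adj <- matrix(0L, n, n)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  binary_network(adj, sparsity = sparsity, subject_id = cm$subject_id,
                 region_ids = cm$region_ids)
}

#' Binary network family over a sparsity grid
#'
#' One network per grid value. Because every grid value selects a prefix of
#' the same deterministic edge ranking, families are nested: each edge
#' present at sparsity S is present at every S' > S.
#'
#' @param cm a [connectivity_matrix()].
#' @param grid a [sparsity_grid()].
#' @param edge_sign passed to [threshold_by_sparsity()].
#' @return list of [binary_network()] in grid order.
#' @export
build_network_family <- function(cm, grid = sparsity_grid(),
                                 edge_sign = c("positive", "absolute")) {
  stopifnot(inherits(grid, "sparsity_grid"))
  edge_sign <- match.arg(edge_sign)
  lapply(grid$values, function(s)
    threshold_by_sparsity(cm, s, edge_sign = edge_sign))
}
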