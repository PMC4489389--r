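# Graph-topology metrics of binary undirected networks.
#
# Conventions, chosen for 90-node networks that can fragment at low density:
#  - characteristic path length averages over *finite-distance* pairs and
#    reports the unreachable-pair count separately (a harmonic-mean variant,
#    1/E_glob, is available via `disconnected = "harmonic"`); this keeps Lp
#    and E_glob distinct, non-redundant summaries on disconnected graphs
#  - nodal clustering is 0 (not dropped) for degree < 2, so the network mean
#    stays defined at low sparsity
#  - local efficiency of a node is the global efficiency of the subgraph
#    induced by its neighbours (Latora-Marchiori operationalization)

metrics_cache <- function(g) {
  stopifnot(inherits(g, "binary_network"))
  graph_metrics_cpp(g$adjacency)
}

#' All-pairs shortest path lengths
#'
#' Unweighted shortest-path distances by breadth-first search; unreachable
#' pairs are `Inf`, the diagonal is 0.
#'
#' @param g a [binary_network()].
#' @return numeric distance matrix with region labels.
#' @export
shortest_path_lengths <- function(g) {
  stopifnot(inherits(g, "binary_network"))
  d <- bfs_distances_cpp(g$adjacency)
  d[d < 0] <- Inf
  storage.mode(d) <- "double"
  dimnames(d) <- list(g$region_ids, g$region_ids)
  d
}

#' Nodal clustering coefficient
#'
#' Fraction of a node's neighbour pairs that are themselves connected
#' (Watts-Strogatz); 0 for degree < 2.
#'
#' @param g a [binary_network()].
#' @param node node label or index; `NULL` returns the full vector.
#' @return clustering value(s) in `[0, 1]`.
#' @export
nodal_clustering <- function(g, node = NULL) {
  m <- metrics_cache(g)
  v <- stats::setNames(m$clustering, g$region_ids)
  if (is.null(node)) return(v)
  v[[resolve_node(g, node)]]
}

#' Characteristic path length
#'
#' Mean shortest-path distance. With `disconnected = "exclude"` (default)
#' the mean is over finite-distance unordered pairs and the unreachable-pair
#' count is attached as attribute `n_unreachable_pairs`; with `"harmonic"`
#' it is `1 / E_glob`.
#'
#' @param g a [binary_network()].
#' @param disconnected convention for unreachable pairs.
#' @return Lp, with attribute `n_unreachable_pairs`.
#' @export
characteristic_path_length <- function(g,
                                       disconnected = c("exclude", "harmonic")) {
  disconnected <- match.arg(disconnected)
  if (g$n_edges == 0) stop_fcnet("Lp undefined: network has no edges")
  m <- metrics_cache(g)
  lp <- if (disconnected == "exclude") m$lp else 1 / m$eglob
  structure(lp, n_unreachable_pairs = m$n_unreachable_pairs)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance
#' (`1/Inf = 0`); 0 for an edgeless graph.
#'
#' @param g a [binary_network()].
#' @return E_glob in `[0, 1]`.
#' @export
global_efficiency <- function(g) metrics_cache(g)$eglob

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbours (the
#' node itself removed); 0 for degree < 2. With `node = NULL` returns the
#' full nodal vector; `mean()` of that vector is the network E_loc.
#'
#' @param g a [binary_network()].
#' @param node node label or index; `NULL` returns the full vector.
#' @return local efficiency value(s) in `[0, 1]`.
#' @export
local_efficiency <- function(g, node = NULL) {
  m <- metrics_cache(g)
  v <- stats::setNames(m$nodal_eloc, g$region_ids)
  if (is.null(node)) return(v)
  v[[resolve_node(g, node)]]
}

#' Whole-network metric summary
#'
#' @param g a [binary_network()].
#' @param disconnected Lp convention, see [characteristic_path_length()].
#' @return list with `cp`, `lp`, `eglob`, `eloc`, `n_unreachable_pairs`.
#' @export
global_metrics <- function(g, disconnected = c("exclude", "harmonic")) {
  disconnected <- match.arg(disconnected)
  m <- metrics_cache(g)
  lp <- if (disconnected == "exclude") m$lp else 1 / m$eglob
  list(cp = m$cp, lp = lp, eglob = m$eglob, eloc = m$eloc,
       n_unreachable_pairs = m$n_unreachable_pairs)
}

#' Nodal metric table
#'
#' @param g a [binary_network()].
#' @return tibble with one row per region: degree, clustering, nodal path
#'   length (mean distance to reachable nodes), nodal global efficiency and
#'   nodal local efficiency.
#' @export
nodal_metrics <- function(g) {
  m <- metrics_cache(g)
  tibble::tibble(
    region = g$region_ids, degree = as.integer(m$degree),
    clustering = m$clustering, lp = m$nodal_lp,
    eglob = m$nodal_eglob, eloc = m$nodal_eloc)
}

#' Metric curves across the sparsity grid
#'
#' Evaluates the four topological metrics for every network of a nested
#' family, producing long-format curves ready for AUC summarisation and
#' group statistics.
#'
#' @param family list of [binary_network()] covering the grid (as produced
#'   by [build_network_family()]).
#' @param grid the [sparsity_grid()] the family was built on.
#' @param include_nodal also assemble per-region curves (default TRUE).
#' @param disconnected Lp convention, see [characteristic_path_length()].
#' @return list with `global` (tibble: subject_id, metric, sparsity, value;
#'   metrics `Cp`, `Lp`, `Eglob`, `Eloc`), `nodal` (tibble: subject_id,
#'   region, metric, sparsity, value, or NULL) and `unreachable` (tibble:
#'   subject_id, sparsity, n_unreachable_pairs).
#' @export
compute_metric_curves <- function(family, grid, include_nodal = TRUE,
                                  disconnected = c("exclude", "harmonic")) {
  stopifnot(inherits(grid, "sparsity_grid"))
  disconnected <- match.arg(disconnected)
  fam_s <- vapply(family, function(g) g$sparsity, numeric(1))
  idx <- match_num(grid$values, fam_s)
  if (anyNA(idx))
    stop_fcnet("family does not cover grid value(s): %s",
               paste(grid$values[is.na(idx)], collapse = ", "))
  family <- family[idx]

  g1 <- family[[1]]
  n_s <- length(grid$values)
  glob <- vector("list", n_s)
  nod <- if (include_nodal) vector("list", n_s) else NULL
  unreach <- numeric(n_s)
  for (i in seq_len(n_s)) {
    m <- metrics_cache(family[[i]])
    lp <- if (disconnected == "exclude") m$lp else 1 / m$eglob
    glob[[i]] <- tibble::tibble(
      subject_id = g1$subject_id,
      metric = c("Cp", "Lp", "Eglob", "Eloc"),
      sparsity = grid$values[i],
      value = c(m$cp, lp, m$eglob, m$eloc))
    unreach[i] <- m$n_unreachable_pairs
    if (include_nodal) {
      nod[[i]] <- tibble::tibble(
        subject_id = g1$subject_id,
        region = rep(g1$region_ids, 4),
        metric = rep(c("Cp", "Lp", "Eglob", "Eloc"), each = g1$n_nodes),
        sparsity = grid$values[i],
        value = c(m$clustering, m$nodal_lp, m$nodal_eglob, m$nodal_eloc))
    }
  }
  list(global = dplyr::bind_rows(glob),
       nodal = if (include_nodal) dplyr::bind_rows(nod) else NULL,
       unreachable = tibble::tibble(subject_id = g1$subject_id,
                                    sparsity = grid$values,
                                    n_unreachable_pairs = unreach))
}
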