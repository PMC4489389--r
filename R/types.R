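#' Regional time-series container
#'
#' Holds one subject's region-by-timepoint BOLD signal matrix together with
#' the sampling interval and region labels. This is the pipeline's raw input:
#' each row is the averaged time series of one atlas region.
#'
#' @param data numeric matrix, regions in rows, timepoints in columns.
#' @param subject_id scalar character identifier.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @param region_ids character vector of region labels; defaults to the
#'   rownames of `data` or `R1..Rn`.
#' @return an object of class `time_series_matrix`.
#' @export
time_series_matrix <- function(data, subject_id = "subject",
                               tr_seconds = 2.0, region_ids = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_fcnet("time series data must be a numeric matrix")
  if (anyNA(data) || any(!is.finite(data)))
    stop_fcnet("time series for '%s' contains missing or non-finite values",
               subject_id)
  if (nrow(data) < 2) stop_fcnet("need at least 2 regions, got %d", nrow(data))
  if (ncol(data) < 8) stop_fcnet("need at least 8 timepoints, got %d", ncol(data))
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop_fcnet("tr_seconds must be positive")
  region_ids <- region_ids %||% rownames(data) %||%
    paste0("R", seq_len(nrow(data)))
  if (length(region_ids) != nrow(data))
    stop_fcnet("region_ids length (%d) does not match region count (%d)",
               length(region_ids), nrow(data))
  rownames(data) <- region_ids
  structure(
    list(subject_id = subject_id, data = data,
         tr_seconds = tr_seconds, region_ids = region_ids),
    class = "time_series_matrix")
}

#' @export
print.time_series_matrix <- function(x, ...) {
  cat(sprintf("<time_series_matrix> %s: %d regions x %d timepoints, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Functional connectivity matrix
#'
#' Symmetric region-by-region Pearson correlation matrix. The diagonal is
#' stored as zero and never treated as an edge.
#'
#' @param r symmetric numeric matrix of correlations in `[-1, 1]`.
#' @param subject_id scalar character identifier.
#' @param region_ids region labels (defaults to rownames).
#' @return an object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(r, subject_id = "subject", region_ids = NULL) {
  if (!is.matrix(r) || !is.numeric(r) || nrow(r) != ncol(r))
    stop_fcnet("r must be a square numeric matrix")
  if (anyNA(r) || any(!is.finite(r)))
    stop_fcnet("connectivity matrix contains non-finite values")
  if (max(abs(r - t(r))) > 1e-10) stop_fcnet("connectivity matrix is not symmetric")
  if (max(abs(r)) > 1 + 1e-10) stop_fcnet("correlations must lie in [-1, 1]")
  diag(r) <- 0
  region_ids <- region_ids %||% rownames(r) %||% paste0("R", seq_len(nrow(r)))
  dimnames(r) <- list(region_ids, region_ids)
  structure(
    list(subject_id = subject_id, r = r, region_ids = region_ids),
    class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s: %d x %d, mean off-diagonal r = %.3f\n",
              x$subject_id, nrow(x$r), ncol(x$r),
              mean(x$r[upper.tri(x$r)])))
  invisible(x)
}

#' Binary undirected network at one sparsity
#'
#' Unweighted, undirected graph over a fixed node set, produced by
#' sparsity-thresholding a connectivity matrix. The node set is always the
#' full region list; isolated nodes are kept.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param sparsity the nominal sparsity (edge density) value.
#' @param subject_id scalar character identifier.
#' @param region_ids region labels (defaults to rownames).
#' @return an object of class `binary_network` with fields `adjacency`,
#'   `sparsity`, `n_nodes`, `n_edges`.
#' @export
binary_network <- function(adjacency, sparsity = NA_real_,
                           subject_id = "subject", region_ids = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop_fcnet("adjacency must be a square matrix")
  storage.mode(adjacency) <- "integer"
  if (!all(adjacency %in% c(0L, 1L))) stop_fcnet("adjacency must be 0/1")
  if (any(diag(adjacency) != 0L)) stop_fcnet("self-loops are not allowed")
  if (!identical(adjacency, t(adjacency)))
    stop_fcnet("adjacency must be symmetric")
  region_ids <- region_ids %||% rownames(adjacency) %||%
    paste0("R", seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(region_ids, region_ids)
  structure(
    list(subject_id = subject_id, sparsity = sparsity, adjacency = adjacency,
         n_nodes = nrow(adjacency), n_edges = sum(adjacency) %/% 2L,
         region_ids = region_ids),
    class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %s: N = %d, K = %d edges (sparsity %s)\n",
              x$subject_id, x$n_nodes, x$n_edges,
              ifelse(is.na(x$sparsity), "?", format(x$sparsity))))
  invisible(x)
}

# resolve a node given as label or 1-based index; lookup error otherwise
resolve_node <- function(g, node) {
  if (is.character(node)) {
    i <- match(node, g$region_ids)
    if (is.na(i)) stop_fcnet("unknown node '%s'", node)
    return(i)
  }
  if (is.numeric(node) && node >= 1 && node <= g$n_nodes) return(as.integer(node))
  stop_fcnet("unknown node '%s'", format(node))
}
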