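#' Null-ensemble specification
#'
#' Controls the degree-matched random-network ensemble used to normalize
#' small-world metrics.
#'
#' @param n_random number of null networks (default 100).
#' @param n_swaps_per_edge rewiring intensity: the rewiring performs
#'   `n_swaps_per_edge * K` attempted double-edge swaps. The special value 0
#'   is a test hook meaning "use the observed graph itself as its ensemble"
#'   (so gamma = lambda = 1 exactly).
#' @param seed RNG seed for the ensemble; `NULL` uses the current RNG state.
#' @return an object of class `null_ensemble_spec`.
#' @export
null_ensemble_spec <- function(n_random = 100, n_swaps_per_edge = 10,
                               seed = NULL) {
  if (n_random < 1) stop_fcnet("n_random must be >= 1")
  if (n_swaps_per_edge < 0) stop_fcnet("n_swaps_per_edge must be >= 0")
  structure(list(n_random = as.integer(n_random),
                 n_swaps_per_edge = as.integer(n_swaps_per_edge),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "null_ensemble_spec")
}

#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Randomizes a network by repeated double-edge swaps that preserve every
#' node's degree exactly; swaps creating self-loops or duplicate edges are
#' rejected. Uses R's RNG stream (seed via `spec$seed` or the caller's
#' `set.seed`). If the degree sequence admits no alternative simple graph
#' (e.g. a triangle), the input is returned with attribute
#' `rewire_unchanged = TRUE`.
#'
#' @param g a [binary_network()] with at least 2 edges.
#' @param spec a [null_ensemble_spec()]; only `n_swaps_per_edge` (and
#'   `seed`, if set) are used.
#' @return a rewired [binary_network()] with identical degree sequence.
#' @export
rewire_degree_preserving <- function(g, spec = null_ensemble_spec()) {
  stopifnot(inherits(g, "binary_network"))
  if (g$n_edges < 2) stop_fcnet("rewiring needs at least 2 edges")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$n_swaps_per_edge == 0) return(g)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  ig <- igraph::rewire(ig, igraph::keeping_degseq(
    loops = FALSE, niter = spec$n_swaps_per_edge * g$n_edges))
  adj <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE))
  storage.mode(adj) <- "integer"
  out <- binary_network(adj, sparsity = g$sparsity,
                        subject_id = g$subject_id, region_ids = g$region_ids)
  if (identical(out$adjacency, g$adjacency))
    attr(out, "rewire_unchanged") <- TRUE
  out
}

#' Small-world indices against a degree-matched null ensemble
#'
#' gamma = Cp / mean(Cp of nulls); lambda = Lp / mean(Lp of nulls);
#' sigma = gamma / lambda. Null Lp uses the identical finite-pair
#' convention as the observed Lp, so disconnection affects numerator and
#' denominator the same way.
#'
#' @param g a [binary_network()] with at least one finite-distance pair.
#' @param spec a [null_ensemble_spec()].
#' @param disconnected Lp convention, see [characteristic_path_length()].
#' @return list with `gamma`, `lambda`, `sigma`, `cp`, `lp`,
#'   `cp_random_mean`, `cp_random_sd`, `lp_random_mean`, `lp_random_sd`,
#'   `n_random`.
#' @export
small_world_indices <- function(g, spec = null_ensemble_spec(),
                                disconnected = c("exclude", "harmonic")) {
  disconnected <- match.arg(disconnected)
  obs <- global_metrics(g, disconnected = disconnected)
  if (!is.finite(obs$lp)) stop_fcnet("lambda undefined: no finite-distance pair")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  spec_noseed <- spec
  spec_noseed$seed <- NULL
  cps <- numeric(spec$n_random)
  lps <- numeric(spec$n_random)
  for (i in seq_len(spec$n_random)) {
    gr <- rewire_degree_preserving(g, spec_noseed)
    mr <- global_metrics(gr, disconnected = disconnected)
    cps[i] <- mr$cp
    lps[i] <- mr$lp
  }
  gamma <- obs$cp / mean(cps)
  lambda <- obs$lp / mean(lps)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp = obs$cp, lp = obs$lp,
       cp_random_mean = mean(cps), cp_random_sd = sd(cps),
       lp_random_mean = mean(lps), lp_random_sd = sd(lps),
       n_random = spec$n_random)
}

#' Classify small-world regime across the sparsity grid
#'
#' A sparsity value is flagged small-world for a group when the group-mean
#' gamma exceeds `gamma_min` and the group-mean lambda stays at or below
#' `lambda_max`. The literature gives no single numeric cutoff ("gamma > 1,
#' lambda approximately 1"); the defaults make that operational and are
#' configurable.
#'
#' @param indices tibble with columns `group`, `sparsity`, `gamma`,
#'   `lambda` (one row per subject x sparsity).
#' @param grid the [sparsity_grid()].
#' @param gamma_min,lambda_max classification cutoffs.
#' @return list with `table` (group x sparsity means and flag) and `ranges`
#'   (per group, the longest contiguous flagged sparsity range, or NA).
#' @export
classify_small_world <- function(indices, grid, gamma_min = 1,
                                 lambda_max = 1.1) {
  stopifnot(inherits(grid, "sparsity_grid"))
  tab <- indices |>
    dplyr::group_by(.data$group, .data$sparsity) |>
    dplyr::summarise(mean_gamma = mean(.data$gamma),
                     mean_lambda = mean(.data$lambda), .groups = "drop") |>
    dplyr::mutate(small_world = .data$mean_gamma > gamma_min &
                    .data$mean_lambda <= lambda_max) |>
    dplyr::arrange(.data$group, .data$sparsity)
  ranges <- tab |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(range = list(longest_run(.data$sparsity,
                                              .data$small_world)),
                     .groups = "drop") |>
    tidyr::unnest_wider("range")
  list(table = tab, ranges = ranges)
}

# longest contiguous TRUE run; returns its sparsity endpoints
longest_run <- function(sparsity, flag) {
  if (!any(flag)) return(list(s_lo = NA_real_, s_hi = NA_real_, n = 0L))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values)[which.max(r$lengths[r$values])]
  list(s_lo = sparsity[starts[i]], s_hi = sparsity[ends[i]],
       n = as.integer(r$lengths[i]))
}
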