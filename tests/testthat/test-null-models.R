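test_that("rewiring preserves the degree sequence exactly", {
  set.seed(41)
  for (rep in 1:10) {
    adj <- random_adjacency(25, 0.2)
    g <- make_net(adj)
    gr <- rewire_degree_preserving(g, null_ensemble_spec(n_swaps_per_edge = 10))
    expect_identical(unname(rowSums(gr$adjacency)),
                     unname(rowSums(g$adjacency)))
    expect_identical(gr$n_edges, g$n_edges)
    expect_true(all(diag(gr$adjacency) == 0L))
  }
})

test_that("a triangle is returned unchanged and flagged", {
  tri <- make_net(adj_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3))))
  set.seed(42)
  out <- rewire_degree_preserving(tri, null_ensemble_spec())
  expect_identical(out$adjacency, tri$adjacency)
  expect_true(isTRUE(attr(out, "rewire_unchanged")))
})

test_that("zero-swap hook makes the graph its own null: gamma = lambda = sigma = 1", {
  set.seed(43)
  g <- make_net(random_adjacency(20, 0.3))
  sw <- small_world_indices(g, null_ensemble_spec(n_random = 1,
                                                  n_swaps_per_edge = 0))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("sigma is exactly gamma over lambda and ensemble stats are returned", {
  set.seed(44)
  g <- make_net(random_adjacency(30, 0.25))
  sw <- small_world_indices(g, null_ensemble_spec(n_random = 20, seed = 7))
  expect_identical(sw$sigma, sw$gamma / sw$lambda)
  expect_true(sw$cp_random_sd >= 0 && sw$lp_random_sd >= 0)
  # same seed reproduces the ensemble
  sw2 <- small_world_indices(g, null_ensemble_spec(n_random = 20, seed = 7))
  expect_identical(sw, sw2)
})

test_that("an Erdos-Renyi graph is its own null up to fluctuation", {
  set.seed(45)
  g <- make_net(random_adjacency(90, 0.18))
  sw <- small_world_indices(g, null_ensemble_spec(n_random = 100, seed = 45))
  expect_gt(sw$gamma, 0.8); expect_lt(sw$gamma, 1.2)
  expect_gt(sw$lambda, 0.95); expect_lt(sw$lambda, 1.05)
})

test_that("a Watts-Strogatz ring is detected as small-world", {
  set.seed(46)
  ws <- igraph::simplify(igraph::sample_smallworld(1, 90, 5, 0.1))
  g <- make_net(matrix(as.integer(as.matrix(
    igraph::as_adjacency_matrix(ws, sparse = FALSE))), 90, 90))
  sw <- small_world_indices(g, null_ensemble_spec(n_random = 50, seed = 46))
  expect_gt(sw$gamma, 1.5)
  expect_lt(sw$lambda, 1.5)
  expect_gt(sw$sigma, 1)
})

test_that("gamma and lambda are invariant under node relabeling (up to ensemble noise)", {
  set.seed(47)
  adj <- random_adjacency(40, 0.2)
  perm <- sample(40)
  s1 <- small_world_indices(make_net(adj),
                            null_ensemble_spec(n_random = 50, seed = 1))
  s2 <- small_world_indices(make_net(adj[perm, perm]),
                            null_ensemble_spec(n_random = 50, seed = 2))
  expect_equal(s1$cp, s2$cp, tolerance = 1e-12)  # observed metrics invariant
  expect_equal(s1$lp, s2$lp, tolerance = 1e-12)
  se <- s1$cp_random_sd / sqrt(50)
  expect_lt(abs(s1$cp_random_mean - s2$cp_random_mean), 5 * se)
})

test_that("ensemble-mean standard error shrinks as 1/sqrt(n_random)", {
  set.seed(48)
  g <- make_net(random_adjacency(60, 0.15))
  s25 <- small_world_indices(g, null_ensemble_spec(n_random = 25, seed = 3))
  s100 <- small_world_indices(g, null_ensemble_spec(n_random = 100, seed = 3))
  ratio <- (s100$cp_random_sd / sqrt(100)) / (s25$cp_random_sd / sqrt(25))
  expect_lt(abs(ratio - 0.5), 0.2)
})

test_that("small-world classification flags the right regimes and reports ranges", {
  grid <- sparsity_grid(0.1, 0.3, 0.1)
  mk <- function(gam, lam) tidyr::expand_grid(
    group = "patient", subject_id = c("a", "b"),
    sparsity = grid$values) |>
    dplyr::mutate(gamma = gam, lambda = lam, sigma = gam / lam)
  all_sw <- classify_small_world(mk(2, 1), grid)
  expect_true(all(all_sw$table$small_world))
  expect_equal(all_sw$ranges$s_lo, 0.1)
  expect_equal(all_sw$ranges$s_hi, 0.3)
  none <- classify_small_world(mk(0.9, 1), grid)
  expect_false(any(none$table$small_world))
  expect_true(is.na(none$ranges$s_lo))
})
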