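test_that("nodal clustering matches hand-computed fixtures", {
  expect_equal(unname(nodal_clustering(triangle())), rep(1, 3))
  expect_equal(unname(nodal_clustering(star5())), rep(0, 5))
  expect_equal(unname(nodal_clustering(chorded_cycle())),
               c(2 / 3, 1, 2 / 3, 1))
  expect_equal(global_metrics(chorded_cycle())$cp, 5 / 6)
  expect_error(nodal_clustering(triangle(), "nope"), "unknown node")
})

test_that("shortest paths match hand fixtures and a Floyd-Warshall oracle", {
  d <- shortest_path_lengths(path3())
  expect_equal(d[1, 3], 2)
  expect_equal(d[1, 2], 1)
  dk <- shortest_path_lengths(k4())
  expect_true(all(dk[upper.tri(dk)] == 1))

  set.seed(31)
  for (rep in 1:5) {
    adj <- random_adjacency(20, 0.15)
    g <- make_net(adj)
    expect_equal(unname(shortest_path_lengths(g)),
                 unname(oracle_fw_distances(adj)))
  }
})

test_that("characteristic path length uses the finite-pair convention", {
  expect_equal(as.numeric(characteristic_path_length(path3())), 4 / 3)
  expect_equal(as.numeric(characteristic_path_length(k4())), 1)
  lp2 <- characteristic_path_length(two_triangles())
  expect_equal(as.numeric(lp2), 1)
  expect_equal(attr(lp2, "n_unreachable_pairs"), 9)
  expect_error(characteristic_path_length(make_net(matrix(0L, 3, 3))),
               "no edges")
})

test_that("global and local efficiency match hand fixtures", {
  expect_equal(global_efficiency(k4()), 1)
  expect_equal(global_efficiency(make_net(matrix(0L, 4, 4))), 0)
  expect_equal(global_efficiency(path3()), 5 / 6)
  expect_equal(unname(local_efficiency(k4())), rep(1, 4))
  expect_equal(unname(local_efficiency(star5())), rep(0, 5))
  # chorded cycle, node A: neighbour subgraph B-C-D is a path -> 5/6
  expect_equal(local_efficiency(chorded_cycle(), 1), 5 / 6)
})

test_that("all four metrics match the brute-force oracle on random graphs", {
  set.seed(32)
  worst <- 0
  for (rep in 1:100) {
    n <- sample(5:25, 1)
    adj <- random_adjacency(n, stats::runif(1, 0.1, 0.6))
    g <- make_net(adj)
    o <- oracle_metrics(adj)
    m <- global_metrics(g)
    worst <- max(worst,
                 abs(m$cp - o$cp),
                 if (is.finite(o$lp)) abs(m$lp - o$lp) else 0,
                 abs(m$eglob - o$eglob), abs(m$eloc - o$eloc),
                 abs(m$n_unreachable_pairs - o$n_unreachable_pairs),
                 max(abs(unname(nodal_clustering(g)) - o$clustering)),
                 max(abs(unname(local_efficiency(g)) - o$nodal_eloc)))
  }
  expect_lt(worst, 1e-12)
})

test_that("distances agree with an independent graph library", {
  set.seed(33)
  adj <- random_adjacency(30, 0.12)
  g <- make_net(adj)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  expect_equal(unname(shortest_path_lengths(g)),
               unname(igraph::distances(ig)))
})

test_that("global efficiency is monotone under edge addition; Lp is not 1/Eglob", {
  set.seed(34)
  adj <- random_adjacency(15, 0.2)
  g <- make_net(adj)
  e0 <- global_efficiency(g)
  free <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
  pick <- free[sample(nrow(free), 1), ]
  adj2 <- adj
  adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
  expect_gte(global_efficiency(make_net(adj2)), e0)

  # finite-pair Lp and 1/E_glob are different summaries off the complete graph
  expect_false(isTRUE(all.equal(
    as.numeric(characteristic_path_length(path3())),
    1 / global_efficiency(path3()))))
})

test_that("metrics are invariant under node relabeling", {
  set.seed(35)
  adj <- random_adjacency(12, 0.3)
  perm <- sample(12)
  g <- make_net(adj)
  gp <- make_net(adj[perm, perm])
  mg <- global_metrics(g)
  mp <- global_metrics(gp)
  expect_equal(mp$cp, mg$cp)
  expect_equal(mp$lp, mg$lp)
  expect_equal(mp$eglob, mg$eglob)
  expect_equal(mp$eloc, mg$eloc)
})

test_that("nodal and whole-network summaries are consistent", {
  set.seed(36)
  adj <- random_adjacency(18, 0.25)
  g <- make_net(adj)
  nm <- nodal_metrics(g)
  m <- global_metrics(g)
  expect_equal(mean(nm$clustering), m$cp)
  expect_equal(mean(nm$eglob), m$eglob)  # mean ordered-pair inverse distance
  expect_equal(mean(nm$eloc), m$eloc)
  expect_equal(nm$degree, unname(rowSums(adj)))
})

test_that("metric curves cover the grid and obey monotonicity where guaranteed", {
  set.seed(37)
  co <- generate_cohort(quick_spec(37, n_patients = 1, n_controls = 1))
  grid <- sparsity_grid()
  cm <- correlation_matrix(co$series[[1]])
  fam <- build_network_family(cm, grid)
  expect_length(fam, 36)
  cc <- compute_metric_curves(fam, grid)
  eg <- cc$global$value[cc$global$metric == "Eglob"]
  expect_true(all(diff(eg) >= -1e-12))  # theorem: edges never lengthen paths
  cp <- cc$global$value[cc$global$metric == "Cp"]
  expect_gt(cp[36], cp[1])  # statistical trend on modular data (not stepwise)
  expect_error(compute_metric_curves(fam[-3], grid), "cover")
})

test_that("complete graph at maximal sparsity has all metrics equal to 1", {
  cm <- cm_from_upper(stats::runif(10, 0.5, 0.9), 5)
  g <- threshold_by_sparsity(cm, 0.999)  # K = 10 = complete
  m <- global_metrics(g)
  expect_equal(m$cp, 1)
  expect_equal(m$lp, 1)
  expect_equal(m$eglob, 1)
  expect_equal(m$eloc, 1)
})
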