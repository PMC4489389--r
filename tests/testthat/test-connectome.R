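test_that("correlation matrix matches the Pearson definition", {
  base <- sin(seq(0, 20, length.out = 50))
  ts <- time_series_matrix(rbind(base, base, -base), tr_seconds = 2)
  cm <- correlation_matrix(ts)
  expect_equal(cm$r[1, 2], 1)
  expect_equal(cm$r[1, 3], -1)
  expect_equal(diag(cm$r), rep(0, 3), ignore_attr = TRUE)

  # 3 regions x 5 timepoints fixture against the brute-force definition
  x <- matrix(c(1.2, -0.4, 2.2, 0.1, 0.9,
                0.3, 1.7, -1.1, 0.6, 0.2,
                -2.0, 0.8, 0.5, 1.4, -0.7), 3, 5, byrow = TRUE)
  # 5 timepoints is below the container minimum of 8; pad by repetition,
  # which leaves Pearson r of the repeated block unchanged
  xx <- cbind(x, x)
  cm2 <- correlation_matrix(time_series_matrix(xx))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(cm2$r[i, j], oracle_pearson(xx[i, ], xx[j, ]),
                 tolerance = 1e-12)
  expect_equal(cm2$r, t(cm2$r))
})

test_that("zero-variance regions are rejected by name", {
  ts <- time_series_matrix(rbind(rep(1, 20), rnorm(20)),
                           region_ids = c("FLAT", "OK"))
  expect_error(correlation_matrix(ts), "FLAT")
})

test_that("thresholding keeps exactly the top-K positive correlations", {
  # N = 4: upper-triangle order (1,2),(1,3),(2,3),(1,4),(2,4),(3,4)
  cm <- cm_from_upper(c(0.9, 0.1, 0.8, 0.3, 0.2, 0.7), 4)
  g <- threshold_by_sparsity(cm, 0.5)   # K = round(0.5*6) = 3
  expect_equal(g$n_edges, 3L)
  expect_equal(g$adjacency[1, 2], 1L)
  expect_equal(g$adjacency[2, 3], 1L)
  expect_equal(g$adjacency[3, 4], 1L)
  expect_equal(g$adjacency[1, 3] + g$adjacency[1, 4] + g$adjacency[2, 4], 0L)

  # all r > 0 at maximal S: complete graph
  cmp <- cm_from_upper(c(0.9, 0.1, 0.8, 0.3, 0.2, 0.7), 4)
  gfull <- threshold_by_sparsity(cmp, 0.999)
  expect_equal(gfull$n_edges, 6L)
  expect_true(all(gfull$adjacency[upper.tri(gfull$adjacency)] == 1L))
})

test_that("ties at the K-th value break lexicographically and deterministically", {
  # (1,2)=0.9, (1,3)=0.5, (2,3)=0.5, (1,4)=0.5, rest small; K = 2
  cm <- cm_from_upper(c(0.9, 0.5, 0.5, 0.5, 0.01, 0.01), 4)
  g1 <- threshold_by_sparsity(cm, 2 / 6)
  expect_equal(g1$n_edges, 2L)
  expect_equal(g1$adjacency[1, 2], 1L)
  expect_equal(g1$adjacency[1, 3], 1L)  # smallest (i, j) among the tied trio
  g2 <- threshold_by_sparsity(cm, 2 / 6)
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("too few positive correlations raise an informative error", {
  cm <- cm_from_upper(c(0.9, -0.1, -0.8, 0.3, -0.2, -0.7), 4)
  expect_error(threshold_by_sparsity(cm, 0.9), "maximum achievable sparsity")
  # achievable max is 2/6
  expect_error(threshold_by_sparsity(cm, 0.9), "0.3333")
})

test_that("edge-count law holds exactly across the default grid and families nest", {
  set.seed(21)
  ts <- time_series_matrix(matrix(rnorm(40 * 120), 40, 120))
  cm <- correlation_matrix(ts)
  grid <- sparsity_grid()
  expect_length(grid$values, 36)
  fam <- build_network_family(cm, grid)
  n <- 40
  for (i in seq_along(fam)) {
    k_expected <- round(grid$values[i] * n * (n - 1) / 2)
    expect_identical(fam[[i]]$n_edges, as.integer(k_expected))
    expect_lte(abs(2 * fam[[i]]$n_edges / (n * (n - 1)) - grid$values[i]),
               1 / (n * (n - 1)))
    if (i > 1)
      expect_true(all(fam[[i]]$adjacency >= fam[[i - 1]]$adjacency))
  }
  # K at S = 0.18 for N = 90 equals round(0.18 * 4005) = 721
  expect_equal(round(0.18 * 90 * 89 / 2), 721)
})

test_that("thresholding depends only on the rank order of positive correlations", {
  set.seed(22)
  cm <- correlation_matrix(time_series_matrix(matrix(rnorm(15 * 80), 15, 80)))
  cm3 <- connectivity_matrix(cm$r^3, subject_id = cm$subject_id)  # monotone, sign-preserving
  g <- threshold_by_sparsity(cm, 0.2)
  g3 <- threshold_by_sparsity(cm3, 0.2)
  expect_identical(g$adjacency, g3$adjacency)
})

test_that("thresholding is equivariant under region permutation", {
  set.seed(23)
  ts <- time_series_matrix(matrix(rnorm(10 * 60), 10, 60),
                           region_ids = paste0("N", 1:10))
  perm <- sample(10)
  tsp <- time_series_matrix(ts$data[perm, ], region_ids = ts$region_ids[perm])
  g <- threshold_by_sparsity(correlation_matrix(ts), 0.3)
  gp <- threshold_by_sparsity(correlation_matrix(tsp), 0.3)
  expect_identical(unname(gp$adjacency), unname(g$adjacency[perm, perm]))
})

test_that("sparsity grid validates its endpoints", {
  expect_error(sparsity_grid(0, 0.4), "0 < s_min")
  expect_error(sparsity_grid(0.05, 1), "s_max")
  expect_error(sparsity_grid(0.05, 0.403), "lie on the grid")
  single <- sparsity_grid(0.1, 0.1)
  expect_equal(single$values, 0.1)
})
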