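test_that("two-sample t-test matches the textbook pooled formula", {
  set.seed(51)
  x <- rnorm(14, 1, 2)
  y <- rnorm(11, 0, 2)
  res <- two_sample_ttest(x, y)
  # independent closed-form oracle
  df <- length(x) + length(y) - 2
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) / df
  t_o <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(res$t, t_o, tolerance = 1e-10)
  expect_equal(res$df, df)
  expect_equal(res$p, 2 * pt(-abs(t_o), df), tolerance = 1e-10)

  same <- rnorm(5)
  res0 <- two_sample_ttest(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  sep <- two_sample_ttest(c(0, 0, 0, 0) + rnorm(4, 0, 1e-4),
                          c(1, 1, 1, 1) + rnorm(4, 0, 1e-4))
  expect_lt(sep$p, 1e-4)

  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "degenerate")
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("summary-statistics t-test equals the raw-data test on matched data", {
  set.seed(52)
  for (rep in 1:5) {
    x <- rnorm(12); y <- rnorm(9)
    # affine-rescale to exact target summaries
    m1 <- 3.1; s1 <- 1.7; m2 <- 2.2; s2 <- 0.9
    x <- (x - mean(x)) / sd(x) * s1 + m1
    y <- (y - mean(y)) / sd(y) * s2 + m2
    a <- summary_ttest(m1, s1, 12, m2, s2, 9)
    b <- two_sample_ttest(x, y)
    expect_equal(a$t, b$t, tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-10)
  }
  eqz <- summary_ttest(5, 1, 10, 5, 1, 10)
  expect_equal(eqz$t, 0)
  expect_equal(eqz$p, 1)
  expect_error(summary_ttest(1, 0, 5, 2, 0, 5), "degenerate")
})

test_that("published cohort demographics reproduce from printed summaries", {
  tab <- cohort_summary_tests(read_cohort_summary())
  expect_p <- function(var, p) {
    row <- tab[tab$variable == var, ]
    expect_equal(row$p_3dp, p, info = var)
  }
  expect_p("Years of education", 0.060)
  expect_p("ADL", 0.047)
  expect_p("CAMCOG-C memory", 0.003)
  expect_p("Word immediate recall", 0.036)
  expect_p("Stroop (color)", 0.001)
  # every row the table marks reproducible must round to its printed value
  rep_rows <- tab[tab$reproducible & !grepl("^<", tab$printed_p), ]
  expect_equal(rep_rows$p_3dp, as.numeric(rep_rows$printed_p))
})

test_that("chi-square on 2x2 tables matches hand computation", {
  bal <- matrix(10, 2, 2)
  res <- chi_square_2x2(bal)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  tab <- matrix(c(10, 13, 11, 9), 2, 2, byrow = TRUE)
  # hand computation from expected counts
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_hand <- sum((tab - e)^2 / e)
  res2 <- chi_square_2x2(tab)
  expect_equal(res2$statistic, chi_hand, tolerance = 1e-12)
  expect_equal(round(chi_hand, 3), 0.568)

  expect_equal(chi_square_2x2(2 * tab)$statistic, 2 * res2$statistic,
               tolerance = 1e-12)
  expect_true(is.na(chi_square_2x2(tab, method = "fisher")$statistic))
  expect_lt(abs(chi_square_2x2(tab, method = "yates")$statistic),
            res2$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
})

test_that("the permutation test agrees with the t-test on clear effects and is seeded", {
  set.seed(57)
  x <- rnorm(20, 1)
  y <- rnorm(20, 0)
  a <- permutation_test(x, y, n_perm = 500, seed = 3)
  b <- permutation_test(x, y, n_perm = 500, seed = 3)
  expect_identical(a, b)
  expect_equal(a$diff, mean(x) - mean(y))
  # strong separation: permutation p near its minimum, t-test agrees
  big <- permutation_test(x + 10, y, n_perm = 500, seed = 3)
  expect_equal(big$p, 1 / 501)
  expect_lt(two_sample_ttest(x + 10, y)$p, 1e-10)
  # exchangeable data: p well away from significance on average
  null_p <- permutation_test(y, y + 0, n_perm = 200, seed = 4)$p
  expect_gt(null_p, 0.5)
})

test_that("curve AUC matches the trapezoid rule", {
  grid <- sparsity_grid()
  expect_equal(curve_auc(rep(2, 36), grid$values), 0.35 * 2, tolerance = 1e-12)
  s <- seq(0, 1, by = 0.05)
  expect_equal(curve_auc(s, s), 0.5, tolerance = 1e-12)
  set.seed(53)
  v <- rnorm(36)
  expect_equal(curve_auc(v, grid$values), oracle_trapz(grid$values, v),
               tolerance = 1e-12)
  expect_equal(curve_auc(v, grid$values, range = c(0.08, 0.31)),
               oracle_trapz(grid$values[4:27], v[4:27]), tolerance = 1e-12)
  expect_error(curve_auc(v, grid$values, range = c(0.075, 0.31)),
               "not on the grid")
})

test_that("Benjamini-Hochberg behaves as the step-up rule requires", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(54)
  p <- runif(20)
  q <- p.adjust(p, method = "BH")
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # ordering preserved
  expect_equal(p.adjust(rep(0.2, 5), method = "BH"), rep(0.2, 5))
})

test_that("exchangeable groups produce no significant group differences", {
  set.seed(55)
  grid <- sparsity_grid(0.1, 0.3, 0.05)
  subj <- sprintf("s%02d", 1:12)
  pair <- rep(1:6, each = 2)  # patient k and control k share a curve exactly
  curves <- tidyr::expand_grid(subject_id = subj, metric = c("Cp", "Lp"),
                               sparsity = grid$values) |>
    dplyr::mutate(pair = pair[match(subject_id, subj)]) |>
    dplyr::group_by(pair, metric, sparsity) |>
    dplyr::mutate(value = rnorm(1)[1]) |>
    dplyr::ungroup() |>
    dplyr::select(-pair)
  man <- tibble::tibble(subject_id = subj,
                        group = rep(c("patient", "control"), 6))
  res <- compare_groups_over_grid(curves, man, grid)
  expect_false(any(res$significant))
  expect_true(all(res$t == 0))
})

test_that("metric-cognition correlation recovers exact and degenerate cases", {
  set.seed(56)
  grid <- sparsity_grid(0.1, 0.3, 0.05)
  subj <- sprintf("s%02d", 1:15)
  curves <- tidyr::expand_grid(subject_id = subj, metric = "Cp",
                               sparsity = grid$values) |>
    dplyr::group_by(subject_id) |>
    dplyr::mutate(value = rnorm(1) + 0.1 * seq_len(5)) |>
    dplyr::ungroup()
  aucs <- curves |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(auc = curve_auc(value, sparsity))
  scores <- tibble::tibble(subject_id = subj, exact = aucs$auc,
                           flat = 1)
  res <- metric_cognition_correlation(curves, scores, "exact",
                                      range = c(0.1, 0.3))
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_error(metric_cognition_correlation(curves, scores,
                                            c("exact", "flat"),
                                            range = c(0.1, 0.3)),
               "degenerate")
  expect_error(metric_cognition_correlation(
    curves, scores[-1, ], "exact", range = c(0.1, 0.3)), "missing")
})
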