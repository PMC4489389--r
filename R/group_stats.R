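#' Two-sample t-test on raw values
#'
#' Pooled-variance (Student) test by default, matching the convention used
#' for the cohort's printed demographics; Welch available via
#' `var_equal = FALSE`. The sign convention throughout the package is
#' patient-minus-control: pass the patient group as `x`.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return list with `t`, `df`, `p`, `direction` (sign of `mean(x) - mean(y)`).
#' @export
two_sample_ttest <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop_fcnet("each group needs at least 2 observations")
  if (var(x) + var(y) == 0)
    stop_fcnet("degenerate test: zero pooled variance")
  ht <- t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, direction = sign(mean(x) - mean(y)))
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance t-test computed from printed (mean, SD, n) triples, as
#' needed to check published demographic tables. Identical to
#' [two_sample_ttest()] on any raw data having exactly those summaries.
#'
#' @param mean1,sd1,n1 first group's summary triple.
#' @param mean2,sd2,n2 second group's summary triple.
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return list with `t`, `df`, `p`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) stop_fcnet("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop_fcnet("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) stop_fcnet("degenerate test: both SDs are zero")
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Permutation test for a two-group difference in means
#'
#' Seeded label-permutation alternative to the t-test for AUC group
#' comparisons: the observed mean difference is ranked against `n_perm`
#' random relabelings; the two-sided p uses the add-one estimator
#' `(b + 1) / (n_perm + 1)`.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list with `diff` (mean(x) - mean(y)) and `p`.
#' @export
permutation_test <- function(x, y, n_perm = 1000, seed = 1) {
  if (length(x) < 2 || length(y) < 2)
    stop_fcnet("each group needs at least 2 observations")
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  n1 <- length(x)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), n1)
    mean(pool[idx]) - mean(pool[-idx])
  }, numeric(1))
  list(diff = obs, p = (sum(abs(null) >= abs(obs)) + 1) / (n_perm + 1))
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction by default (df = 1);
#' Yates-corrected and Fisher-exact variants are available since published
#' categorical p-values are often ambiguous between the three.
#'
#' @param tab 2x2 matrix of counts.
#' @param method `"pearson"` (default), `"yates"` or `"fisher"`.
#' @return list with `statistic` (NA for Fisher) and `p`.
#' @export
chi_square_2x2 <- function(tab, method = c("pearson", "yates", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop_fcnet("tab must be 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_fcnet("degenerate table: zero marginal")
  if (method == "fisher") {
    return(list(statistic = NA_real_, p = fisher.test(tab)$p.value))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = method == "yates"))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoid-rule integral of a metric curve over a sub-range of the grid,
#' the threshold-free per-subject summary used for group comparison. Both
#' endpoints must lie on the grid.
#'
#' @param values metric values at `sparsity`.
#' @param sparsity ordered grid values.
#' @param range length-2 numeric sub-interval; `NULL` integrates the whole
#'   curve.
#' @return the AUC (scalar).
#' @export
curve_auc <- function(values, sparsity, range = NULL) {
  if (length(values) != length(sparsity))
    stop_fcnet("values and sparsity differ in length")
  o <- order(sparsity)
  sparsity <- sparsity[o]
  values <- values[o]
  if (!is.null(range)) {
    i <- match_num(range, sparsity)
    if (anyNA(i))
      stop_fcnet("range endpoint(s) %s not on the grid",
                 paste(range[is.na(i)], collapse = ", "))
    keep <- seq(min(i), max(i))
    sparsity <- sparsity[keep]
    values <- values[keep]
  }
  if (length(values) < 2) stop_fcnet("AUC needs at least 2 grid points")
  pracma::trapz(sparsity, values)
}

# per-subject AUC table from long-format curves
metric_aucs <- function(curves, range = NULL, by_region = FALSE) {
  keys <- c("subject_id", "metric", if (by_region) "region")
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(auc = curve_auc(.data$value, .data$sparsity, range),
                     .groups = "drop")
}

run_tests <- function(tbl, value_col, patients, controls) {
  tbl |>
    dplyr::summarise(
      res = list(two_sample_ttest(.data[[value_col]][.data$subject_id %in% patients],
                                  .data[[value_col]][.data$subject_id %in% controls])),
      .groups = "drop") |>
    tidyr::unnest_wider("res")
}

#' Group comparison of metric curves
#'
#' Runs patient-versus-control pooled t-tests (sign convention: positive t
#' means higher in patients) for each global metric (a) at every sparsity on
#' the grid, (b) on the per-subject AUC over `auc_range`, and, when nodal
#' curves are supplied, (c) per region at the reporting sparsity. p-values
#' are Benjamini-Hochberg adjusted within each family: across sparsities
#' within a metric for (a), across the global metrics for (b), and across
#' regions within a metric for (c).
#'
#' @param curves long global curves (`subject_id`, `metric`, `sparsity`,
#'   `value`) for all subjects.
#' @param manifest cohort manifest with `subject_id` and `group`
#'   (`"patient"` / `"control"`).
#' @param grid the [sparsity_grid()].
#' @param nodal_curves optional long nodal curves (adds the per-region
#'   comparison).
#' @param fdr_q significance level on adjusted p (default 0.05).
#' @param report_sparsity sparsity at which nodal comparisons are reported
#'   (default 0.18).
#' @param auc_range sub-range for the AUC comparison; `NULL` = whole grid.
#' @param auc set FALSE to skip the AUC comparison (needed on a degenerate
#'   single-threshold grid).
#' @return tibble with columns `comparison` (`per_sparsity`, `auc`,
#'   `nodal`), `metric`, `region`, `sparsity`, `t`, `df`, `p`, `q`,
#'   `direction`, `significant`.
#' @export
compare_groups_over_grid <- function(curves, manifest, grid,
                                     nodal_curves = NULL, fdr_q = 0.05,
                                     report_sparsity = 0.18,
                                     auc_range = NULL, auc = TRUE) {
  stopifnot(inherits(grid, "sparsity_grid"))
  patients <- manifest$subject_id[manifest$group == "patient"]
  controls <- manifest$subject_id[manifest$group == "control"]
  if (length(patients) < 2 || length(controls) < 2)
    stop_fcnet("each group needs at least 2 subjects (got %d / %d)",
               length(patients), length(controls))

  per_s <- curves |>
    dplyr::group_by(.data$metric, .data$sparsity) |>
    run_tests("value", patients, controls) |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(q = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(comparison = "per_sparsity", region = NA_character_)

  auc_t <- NULL
  if (auc) {
    auc_t <- metric_aucs(curves, range = auc_range) |>
      dplyr::group_by(.data$metric) |>
      run_tests("auc", patients, controls) |>
      dplyr::mutate(q = p.adjust(.data$p, method = "BH"),
                    comparison = "auc", region = NA_character_,
                    sparsity = NA_real_)
  }

  nodal_t <- NULL
  if (!is.null(nodal_curves)) {
    i <- match_num(report_sparsity, grid$values)
    if (is.na(i))
      stop_fcnet("report_sparsity %g is not on the grid", report_sparsity)
    nodal_t <- nodal_curves |>
      dplyr::filter(abs(.data$sparsity - report_sparsity) < 1e-8) |>
      dplyr::group_by(.data$metric, .data$region, .data$sparsity) |>
      run_tests("value", patients, controls) |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(q = p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup() |>
      dplyr::mutate(comparison = "nodal")
  }

  dplyr::bind_rows(per_s, auc_t, nodal_t) |>
    dplyr::mutate(significant = .data$q < fdr_q) |>
    dplyr::select(dplyr::all_of(c("comparison", "metric", "region",
                                  "sparsity", "t", "df", "p", "q",
                                  "direction", "significant")))
}

#' Correlation between network metrics and cognition
#'
#' Pearson correlation between each subject's metric AUC over a stated
#' sparsity sub-range and each cognitive score, for global metrics and
#' (optionally) per-region nodal metrics, with BH adjustment across regions
#' within each metric x score family.
#'
#' @param curves long global curves for the subjects to correlate (subset
#'   before calling to restrict to one group).
#' @param scores data frame with `subject_id` and one column per score.
#' @param score_cols character vector naming the score columns.
#' @param range AUC sparsity sub-range (default `c(0.08, 0.31)`).
#' @param nodal_curves optional long nodal curves.
#' @return tibble with `scope` (`global` / `nodal`), `metric`, `region`,
#'   `score`, `r`, `p`, `q`, `n`.
#' @export
metric_cognition_correlation <- function(curves, scores, score_cols,
                                         range = c(0.08, 0.31),
                                         nodal_curves = NULL) {
  miss <- setdiff(c("subject_id", score_cols), names(scores))
  if (length(miss) > 0)
    stop_fcnet("scores lack column(s): %s", paste(miss, collapse = ", "))
  subj <- unique(curves$subject_id)
  if (!all(subj %in% scores$subject_id))
    stop_fcnet("scores missing for subject(s): %s",
               paste(setdiff(subj, scores$subject_id), collapse = ", "))
  for (sc in score_cols) {
    v <- scores[[sc]][scores$subject_id %in% subj]
    if (sd(v) == 0) stop_fcnet("degenerate score '%s': constant vector", sc)
  }

  cor_one <- function(auc_tbl, scope) {
    out <- list()
    for (sc in score_cols) {
      joined <- dplyr::inner_join(auc_tbl, scores[, c("subject_id", sc)],
                                  by = "subject_id")
      keys <- c("metric", if (scope == "nodal") "region")
      res <- joined |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::summarise(
          r = cor(.data$auc, .data[[sc]]),
          p = cor.test(.data$auc, .data[[sc]])$p.value,
          n = dplyr::n(), .groups = "drop") |>
        dplyr::mutate(score = sc, scope = scope)
      out[[sc]] <- res
    }
    dplyr::bind_rows(out)
  }

  glob <- cor_one(metric_aucs(curves, range = range), "global") |>
    dplyr::mutate(region = NA_character_, q = .data$p)
  nod <- NULL
  if (!is.null(nodal_curves)) {
    nod <- cor_one(metric_aucs(nodal_curves, range = range,
                               by_region = TRUE), "nodal") |>
      dplyr::group_by(.data$metric, .data$score) |>
      dplyr::mutate(q = p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  }
  dplyr::bind_rows(glob, nod) |>
    dplyr::select(dplyr::all_of(c("scope", "metric", "region", "score",
                                  "r", "p", "q", "n")))
}
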