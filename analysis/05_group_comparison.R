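#!/usr/bin/env Rscript
# Stage 5: patient-versus-control statistics.
#
# Pooled two-sample t-tests (positive t = higher in patients) for every
# global metric at every sparsity and on the per-subject AUC over the whole
# grid, plus per-region tests at the reporting sparsity S = 0.18;
# Benjamini-Hochberg correction within each family. Also reproduces the
# demographic-table t-tests from printed summary statistics as a check of
# the statistical machinery.

library(fcnet)
suppressMessages(library(dplyr))

out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest("results/filtered/manifest.tsv")
curves <- readr::read_tsv("results/metrics/metric_curves.tsv",
                          show_col_types = FALSE)
nodal <- readr::read_tsv("results/metrics/nodal_curves.tsv",
                         show_col_types = FALSE)
grid <- sparsity_grid()

tests <- compare_groups_over_grid(curves, manifest, grid,
                                  nodal_curves = nodal,
                                  fdr_q = 0.05, report_sparsity = 0.18)
readr::write_tsv(tests, file.path(out, "group_tests.tsv"))

auc <- tests |> filter(comparison == "auc")
cat("AUC group comparison (q = BH-adjusted):\n")
print(as.data.frame(auc[, c("metric", "t", "df", "p", "q", "direction")]),
      digits = 3)

nod_sig <- tests |> filter(comparison == "nodal", significant)
cat(sprintf("\nnodal differences at S = 0.18 passing q < 0.05: %d regions\n",
            nrow(nod_sig)))
if (nrow(nod_sig) > 0)
  print(as.data.frame(head(
    nod_sig[order(nod_sig$q), c("metric", "region", "t", "q")], 15)),
    digits = 3)

cat("\ndemographics from printed summaries (pooled t):\n")
demo <- cohort_summary_tests(read_cohort_summary())
print(as.data.frame(demo[demo$reproducible,
                         c("variable", "t", "p_3dp", "printed_p")]),
      digits = 3)
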