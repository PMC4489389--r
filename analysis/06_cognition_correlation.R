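#!/usr/bin/env Rscript
# Stage 6: metric-cognition correlations within the patient group.
#
# Pearson correlation between each patient's metric AUC over the 0.08-0.31
# sparsity range and the cognitive scores (global battery total and the
# praxis subscore), for global metrics and per-region nodal metrics with
# BH correction across regions.

library(fcnet)
suppressMessages(library(dplyr))

out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest("results/filtered/manifest.tsv")
curves <- readr::read_tsv("results/metrics/metric_curves.tsv",
                          show_col_types = FALSE)
nodal <- readr::read_tsv("results/metrics/nodal_curves.tsv",
                         show_col_types = FALSE)

patients <- manifest$subject_id[manifest$group == "patient"]
cors <- metric_cognition_correlation(
  curves |> filter(subject_id %in% patients),
  manifest, c("camcog_total", "praxis"), range = c(0.08, 0.31),
  nodal_curves = nodal |> filter(subject_id %in% patients))
readr::write_tsv(cors, file.path(out, "correlations.tsv"))

cat("global metric ~ cognition correlations (patients):\n")
print(as.data.frame(cors |> filter(scope == "global") |>
                      select(metric, score, r, p, n)), digits = 3)
sig <- cors |> filter(scope == "nodal", q < 0.05)
cat(sprintf("\nnodal correlations passing q < 0.05: %d\n", nrow(sig)))
if (nrow(sig) > 0)
  print(as.data.frame(head(sig[order(sig$q), ], 10)), digits = 3)
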