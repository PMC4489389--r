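#!/usr/bin/env Rscript
# Stage 2: motion QC and temporal band-pass filtering.
#
# Subjects whose simulated head motion exceeds 3.0 mm translation or 3
# degrees rotation in any direction are excluded (strict inequality: a
# subject exactly at the bound is kept). Remaining series are band-passed
# to 0.01-0.08 Hz with a zero-phase order-4 Butterworth filter.

library(fcnet)

cohort_dir <- "results/cohort"
out <- "results/filtered"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(cohort_dir, "manifest.tsv"))
qc <- apply_motion_qc(manifest, motion_rule())
cat(sprintf("motion QC: kept %d, excluded %d (%s)\n",
            length(qc$kept), length(qc$excluded),
            paste(qc$excluded, collapse = ", ")))

for (id in qc$kept) {
  ts <- read_time_series(file.path(cohort_dir, "timeseries",
                                   paste0(id, ".tsv")), subject_id = id)
  write_time_series(bandpass_filter(ts, bandpass_spec()),
                    file.path(out, paste0(id, ".tsv")))
}
write_manifest(manifest[manifest$subject_id %in% qc$kept, ],
               file.path(out, "manifest.tsv"))
cat(sprintf("band-passed %d subjects to 0.01-0.08 Hz -> %s\n",
            length(qc$kept), out))
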