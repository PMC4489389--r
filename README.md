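# fcnet — small-world analysis of resting-state functional connectomes

fcnet is an R package plus analysis workflow for graph-theoretical study of
resting-state functional connectivity in case–control designs — the kind of
analysis used to ask whether a patient group (here, subcortical vascular
cognitive impairment, SVCI, versus healthy controls) shows disrupted
whole-brain network topology, and whether that disruption tracks cognition.

From each subject's regional BOLD time series (90 atlas regions × 230
volumes), the pipeline:

- applies the final preprocessing steps: motion-based exclusion
  (translation > 3.0 mm or rotation > 3° in any direction) and a zero-phase
  Butterworth band-pass to 0.01–0.08 Hz;
- builds the Pearson correlation connectome and thresholds it into binary
  undirected networks across a sparsity grid 0.05 ≤ S ≤ 0.40 (step 0.01),
  keeping the K = round(S·N(N−1)/2) strongest positive correlations;
- computes clustering coefficient (Cp), characteristic path length (Lp),
  global efficiency (E_glob) and local efficiency (E_loc) at nodal and
  whole-network level, as curves over the grid;
- normalizes against degree-preserving (Maslov–Sneppen) random networks:
  γ = Cp/Cp_rand, λ = Lp/Lp_rand, σ = γ/λ, with a configurable small-world
  classification (group-mean γ > 1, λ ≤ 1.1);
- compares groups with pooled two-sample t-tests per sparsity and on
  per-subject curve AUCs, with Benjamini–Hochberg FDR within each family
  (positive t = higher in patients), and per-region tests at a reporting
  sparsity of 0.18;
- correlates metric AUCs over 0.08–0.31 with cognitive scores.

Because the motivating study's scans are not deposited, the package includes
a first-class synthetic cohort generator (23 patients / 20 controls, modular
covariance, a group effect that weakens within-module coupling in patients,
and cognitive scores linearly coupled to each subject's coupling strength),
so every stage is validated against known ground truth. See the methods
vignette (`vignettes/small-world-connectome-methods.Rmd`) for the model,
conventions, and parameter rationale.

## Worked example

```r
library(fcnet)
library(dplyr)

co   <- generate_cohort(cohort_spec(seed = 20260928), bandlimit = FALSE)
qc   <- apply_motion_qc(co$manifest, motion_rule())
grid <- sparsity_grid()
curves <- bind_rows(lapply(co$series[qc$kept], function(ts)
  compute_metric_curves(
    build_network_family(correlation_matrix(bandpass_filter(ts)), grid),
    grid, include_nodal = FALSE)$global))
tests <- compare_groups_over_grid(curves, co$manifest, grid)
filter(tests, comparison == "auc")
```

which prints (AUC group comparison, q = BH-adjusted):

```
  metric      t df        p        q direction
1     Cp -19.39 40 6.02e-22 1.20e-21        -1
2  Eglob  27.09 40 2.40e-27 9.59e-27         1
3   Eloc -17.24 40 4.05e-20 5.40e-20        -1
4     Lp   5.01 40 1.16e-05 1.16e-05         1
```

— the designed patient deficit is recovered: clustering and local
efficiency are lower and characteristic path length higher in patients
(direction −1/+1 = lower/higher in patients; one of the 43 simulated
subjects was excluded by motion QC). Within patients, the clustering AUC
correlates with the simulated cognitive battery total
(r = 0.65, p = 0.001):

```r
metric_cognition_correlation(
  filter(curves, subject_id %in% co$manifest$subject_id[co$manifest$group == "patient"]),
  co$manifest, "camcog_total", range = c(0.08, 0.31))
```

The package also reproduces, exactly, the published demographic t-tests of
the motivating cohort from printed (mean, SD, n) summaries:

```r
subset(cohort_summary_tests(read_cohort_summary()),
       variable == "Years of education", select = c(t, p_3dp))
#        t  p_3dp
#   -1.936  0.060
```

## Analysis workflow

The `analysis/` scripts run the full study as numbered stages, writing TSV
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # synthetic cohort
Rscript analysis/02_preprocess.R           # motion QC + band-pass
Rscript analysis/03_connectomes_metrics.R  # networks + metric curves
Rscript analysis/04_small_world.R          # gamma/lambda/sigma vs nulls
Rscript analysis/05_group_comparison.R     # t-tests, AUC, FDR, nodal table
Rscript analysis/06_cognition_correlation.R
```

Or equivalently in one call: `run_pipeline(pipeline_config(), "results/run")`.

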