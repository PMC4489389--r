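---
title: "Methods: small-world analysis of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-world analysis of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

fcnet implements the standard graph-theoretical analysis of resting-state
functional connectivity used in clinical connectomics, for case–control
designs such as subcortical vascular cognitive impairment (SVCI) versus
healthy controls. The pipeline starts from regional BOLD time series (one
matrix of 90 atlas regions × 230 volumes per subject, TR = 2 s), and
proceeds:

1. **Preprocessing tail.** Motion-based exclusion (a subject is dropped
   when maximum translation exceeds 3.0 mm *or* maximum rotation exceeds
   3°, strict inequalities) and temporal band-pass filtering to
   0.01–0.08 Hz.
2. **Connectome.** Pearson correlation between every pair of regional
   series; the diagonal is excluded.
3. **Binary networks.** For each sparsity $S$ on the grid
   $0.05 \le S \le 0.40$ (step 0.01, 36 values), the
   $K = \mathrm{round}(S \cdot N(N-1)/2)$ strongest positive correlations
   become edges of an undirected, unweighted graph on the fixed node set.
4. **Topology.** Clustering coefficient $C_p$, characteristic path length
   $L_p$, global efficiency $E_{glob}$, local efficiency $E_{loc}$ — nodal
   and whole-network — as curves over the grid.
5. **Normalization.** Degree-preserving (Maslov–Sneppen) random networks
   give $\gamma = C_p/\bar C_p^{rand}$, $\lambda = L_p/\bar L_p^{rand}$,
   $\sigma = \gamma/\lambda$; a sparsity is classified small-world for a
   group when group-mean $\gamma > 1$ and group-mean $\lambda \le 1.1$.
6. **Inference.** Pooled two-sample t-tests per sparsity and on per-subject
   curve AUCs (positive $t$ = higher in patients); per-region tests at a
   reporting sparsity of 0.18; Benjamini–Hochberg FDR within each family;
   Pearson correlation between metric AUC over 0.08–0.31 and cognitive
   scores.

Because the motivating study deposits no raw scans, a synthetic cohort
generator stands in for data while preserving the full analysis surface:
every stage runs on generated data with known ground truth.

## The synthetic cohort generator

The generator emulates the study design — 23 patients, 20 controls, 90
regions, 230 volumes — not the physiology of SVCI. Regions are assigned to
6 contiguous modules (the last module absorbs any remainder). For subject
$s$, a latent coupling $\rho_s$ is drawn from a Normal around the group
target (controls 0.6, patients 0.3; SD 0.05), truncated to
(between-module level, 0.95). Signals are sampled i.i.d. over time from a
block-constant correlation matrix ($\rho_s$ within modules, 0.1 between),
then white noise (SD 0.2, signal variance 1) is added and the series passes
through the same band-pass filter as real data. Cognitive scores are
linearly coupled to the latent trait:

$$\text{score} = 58 + 60\,\rho_s + \varepsilon,\quad
  \varepsilon \sim N(0, 3^2),$$

which puts group means near 76 (patients) and 94 (controls), matching the
scale of a CAMCOG-like battery; a praxis-like subscore uses
$4.2 + 11\rho_s + N(0, 0.8^2)$. Head-motion summaries are log-normal with
roughly 5% of subjects per axis above the 3.0 exclusion bound, so about one
subject in ten exercises the QC path.

Parameter rationale, chosen once for testability rather than SVCI fidelity
(the study reports no per-subject connectivity variance to emulate):

- `between_r = 0.1`: weak positive background connectivity, enough that
  the top 40% of correlations are well defined at every grid value.
- `noise_sd = 0.2`: attenuates empirical correlations by ~4%
  ($\rho/(1+\sigma^2_{noise})$), representative of measurement noise
  without drowning the modular structure.
- `coupling_sd = 0.05` and `cognition_sd = 3`: give the latent trait a
  clear but not deterministic imprint on cognition
  ($r \approx 0.7$ within a group), so correlation recovery is a
  meaningful test.

What the generator deliberately does **not** emulate: voxel space and
spatial smoothing, hemodynamic autocorrelation (samples are i.i.d. over
time, so only the band-limited effective degrees of freedom are realistic),
anatomically realistic module layout, lesion/WMH structure, and
negative-correlation networks. Passing recovery tests therefore show that
the *pipeline* detects effects of weakened within-module coupling under
realistic noise — they are not evidence about real SVCI physiology.

### Why the group effect has the direction it does

With equal edge counts at a given sparsity, control networks concentrate
edges inside modules (high clustering); at low sparsity they fragment into
modules, so the finite-pair path length is short *within* components while
many pairs are unreachable. Patient networks, with within-module coupling
closer to the background, spread edges more randomly: lower clustering,
but a connected, more random graph whose finite-pair path length spans the
whole network. Cp is therefore lower and Lp AUC higher in patients — the
direction of the motivating clinical finding — while global efficiency,
which scores unreachable pairs as zero, can move the other way on strongly
fragmented synthetic networks.

## Numerical and convention choices

- **Filter.** Order-4 Butterworth band-pass applied forward and backward
  (zero phase, so no lag is introduced before correlation). The band edges
  are the single-pass −3 dB points; the zero-phase response's own −3 dB
  band is slightly narrower (≈0.011–0.074 Hz). Each series is demeaned
  before and after filtering, making DC removal exact. Edge transients are
  suppressed by *symmetric* reflection padding of one filter-settling
  length (where the slowest pole's impulse response decays below 1%);
  sign-flipped (odd) reflection is deliberately avoided because around a
  nonzero endpoint it creates a DC step that excites the filter's slow
  poles and leaks visible transients into 230-point series.
- **Edge selection.** Positive correlations only (the dominant convention
  for binarized resting-state networks; `edge_sign = "absolute"` is
  available). K rounds half away from zero, so realized density is closest
  to nominal; ties at the K-th correlation break by ascending (i, j) pair
  order, making edge sets fully deterministic. No Fisher z-transform:
  thresholding is rank-based, so it would not change edge sets.
- **Disconnected graphs.** $L_p$ is the mean over finite-distance pairs
  with the unreachable-pair count reported alongside (a harmonic
  alternative, $1/E_{glob}$, is available). At sparsity 0.05 a 90-node
  network can fragment; defining $L_p$ via $1/E_{glob}$ would make the two
  metrics redundant, whereas their distinct behaviour on fragmented graphs
  is informative. Nodal clustering and local efficiency are 0 (not
  excluded) for degree < 2, keeping network means defined at low density.
- **Null ensembles.** 100 rewired graphs with 10 attempted double-edge
  swaps per edge by default (config-exposed); swaps creating self-loops or
  duplicate edges are rejected, so degree sequences are conserved exactly.
  Null $L_p$ uses the identical finite-pair convention as the observed
  $L_p$ — mixing conventions would bias $\lambda$. Ensemble seeds derive
  from (base seed, subject, sparsity) via a stable hash, so results are
  independent of execution order. A zero-swap ensemble is a test hook that
  makes a graph its own null ($\gamma = \lambda = 1$ exactly).
- **Small-world cutoff.** The literature's "$\gamma > 1$, $\lambda \approx
  1$" is qualitative; the classifier makes it operational as group-mean
  $\gamma > 1$ and $\lambda \le 1.1$, both configurable.
- **Statistics.** Pooled-variance (Student) t-tests by default — validated
  by exactly reproducing the printed p-values of the motivating cohort's
  demographic table from its (mean, SD, n) triples (0.060, 0.047, 0.003,
  0.036, 0.001); Welch is an option. A handful of that table's printed
  p-values are *not* recoverable from their own printed summaries under
  either test (e.g. a perception subscore whose triples give p ≈ 0.53);
  the bundled summary table flags these rows as non-reproducible and they
  are excluded from validation. Chi-square for 2×2 tables is Pearson
  without continuity correction, with Yates and Fisher variants. FDR is
  Benjamini–Hochberg within each (metric × scope) family. AUC is the
  trapezoid rule; both endpoints must lie on the grid.
- **Determinism.** Every stochastic component is seeded; rerunning the
  pipeline with the same configuration and seed reproduces result tables
  byte for byte. Numeric matrices are written with round-trip-exact
  (`%.17g`) formatting and read back with strtod-based parsing.

## Problem sizes used in validation

The test suite validates metrics against brute-force oracles
(Floyd–Warshall distances, direct neighbour-pair enumeration) on 100
random graphs of up to 25 nodes at 1e-12, and validates recovery on 20
replicate cohorts at the full study geometry (43 subjects × 90 regions ×
230 volumes × 36 sparsities). Null-model calibration uses Erdős–Rényi
graphs (N = 90, p = 0.18; their own null up to fluctuation, so
$\gamma \approx \lambda \approx 1$) and Watts–Strogatz rings (N = 90,
k = 10, rewiring 0.1; strongly small-world, $\sigma > 1$) with 100-null
ensembles. Pipeline determinism is exercised on a 12-subject, 30-region
configuration — smaller than the study geometry because the property being
checked (byte-identical reruns) does not depend on size.

## Known limitations

- Weighted, directed, and FDR-thresholded networks are out of scope, as
  are betweenness/modularity/rich-club metrics.
- The generator's i.i.d.-in-time sampling means temporal autocorrelation
  beyond the band limit is absent; effective degrees of freedom in real
  BOLD data differ.
- The small-world classification depends on the stated cutoffs; with the
  default synthetic design, strongly modular control networks can exceed
  $\lambda = 1.1$ at low sparsity, mirroring the motivating observation
  that small-world attributes emerge only above a minimum density.
- Group comparisons adjust for no covariates (age, education); the
  motivating analysis reports none for the network stage.
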