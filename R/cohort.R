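#' Synthetic cohort specification
#'
#' Parameters of the two-group synthetic resting-state cohort. The generator
#' emulates a patient/control case-control design: per subject, regional
#' signals are drawn from a block-structured (modular) covariance in which
#' within-module coupling carries the group effect, and a cognitive score is
#' linearly coupled to each subject's latent coupling strength. Defaults
#' mirror a 23-patient / 20-control design with 90 atlas regions and 230
#' retained volumes at TR = 2 s.
#'
#' @param n_patients,n_controls group sizes.
#' @param n_regions number of atlas regions (network nodes).
#' @param n_timepoints retained volumes per subject.
#' @param tr_seconds sampling interval in seconds.
#' @param n_modules number of covariance blocks; the last block absorbs any
#'   remainder when `n_regions` is not divisible.
#' @param within_r_control,within_r_patient target within-module correlation
#'   per group; must satisfy
#'   `0 <= between_r < within_r_patient <= within_r_control < 1`.
#' @param between_r baseline between-module correlation.
#' @param noise_sd additive white-noise scale (signal variance is 1).
#' @param coupling_sd SD of the per-subject latent coupling around its group
#'   target (truncated to `(between_r, 0.95)`).
#' @param cognition_intercept,cognition_slope,cognition_sd linear model of
#'   the cognitive total score on the latent coupling:
#'   `score = intercept + slope * coupling + N(0, sd)`.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 23, n_controls = 20, n_regions = 90,
                        n_timepoints = 230, tr_seconds = 2.0, n_modules = 6,
                        within_r_control = 0.6, within_r_patient = 0.3,
                        between_r = 0.1, noise_sd = 0.2, coupling_sd = 0.05,
                        cognition_intercept = 58, cognition_slope = 60,
                        cognition_sd = 3, seed = 1L) {
  counts <- c(n_patients = n_patients, n_controls = n_controls,
              n_regions = n_regions, n_timepoints = n_timepoints,
              n_modules = n_modules)
  for (nm in names(counts)) {
    if (!is.numeric(counts[[nm]]) || counts[[nm]] < 1)
      stop_fcnet("%s must be a positive count (got %s)", nm,
                 format(counts[[nm]]))
  }
  if (n_modules > n_regions)
    stop_fcnet("n_modules (%d) cannot exceed n_regions (%d)",
               n_modules, n_regions)
  if (!(between_r >= 0))
    stop_fcnet("between_r must be >= 0 (got %g)", between_r)
  if (!(between_r < within_r_patient))
    stop_fcnet("between_r (%g) must be < within_r_patient (%g)",
               between_r, within_r_patient)
  if (!(within_r_patient <= within_r_control))
    stop_fcnet("within_r_patient (%g) must be <= within_r_control (%g)",
               within_r_patient, within_r_control)
  if (!(within_r_control < 1))
    stop_fcnet("within_r_control must be < 1 (got %g)", within_r_control)
  if (noise_sd < 0 || coupling_sd < 0 || cognition_sd < 0)
    stop_fcnet("noise_sd, coupling_sd and cognition_sd must be >= 0")
  if (tr_seconds <= 0) stop_fcnet("tr_seconds must be positive")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, n_modules = as.integer(n_modules),
    within_r_control = within_r_control, within_r_patient = within_r_patient,
    between_r = between_r, noise_sd = noise_sd, coupling_sd = coupling_sd,
    cognition_intercept = cognition_intercept,
    cognition_slope = cognition_slope, cognition_sd = cognition_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Module (covariance block) assignment
#'
#' Contiguous assignment of regions to modules; the last module absorbs the
#' remainder when the region count is not divisible.
#'
#' @param n_regions,n_modules counts.
#' @return integer vector of module labels, length `n_regions`.
#' @export
module_assignment <- function(n_regions, n_modules) {
  base <- n_regions %/% n_modules
  sizes <- rep(base, n_modules)
  sizes[n_modules] <- sizes[n_modules] + n_regions %% n_modules
  rep(seq_len(n_modules), times = sizes)
}

# Block-constant correlation target, projected to the nearest
# positive-definite matrix by eigenvalue clipping at 1e-6 and rescaled to
# unit diagonal. Block-constant targets are PD for our parameter ranges, but
# the projection keeps sampling safe under any per-subject perturbation.
block_correlation_matrix <- function(n_regions, modules, within_r, between_r) {
  same <- outer(modules, modules, "==")
  s <- matrix(between_r, n_regions, n_regions)
  s[same] <- within_r
  diag(s) <- 1
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    v <- pmax(e$values, 1e-6)
    s <- e$vectors %*% (v * t(e$vectors))
    d <- 1 / sqrt(diag(s))
    s <- s * outer(d, d)
  }
  s
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  min(max(mean, lo), hi)
}

# log-normal motion draw: each axis has ~5% mass above 3.0, so roughly one
# subject in ten trips the default exclusion rule on either axis
r_motion <- function() rlnorm(1, meanlog = log(3) - 1.645 * 0.8, sdlog = 0.8)

#' Generate a synthetic two-group cohort
#'
#' Draws, per subject, a latent within-module coupling around the group
#' target, samples regional signals from the block-structured covariance,
#' adds white measurement noise, and (by default) band-limits the result
#' through the same zero-phase Butterworth filter used for real data. The
#' manifest records the ground-truth coupling, cognitive scores linearly
#' coupled to it, and simulated motion summaries. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param bandlimit apply the band-pass inside the generator (default TRUE);
#'   set FALSE when the pipeline will run its own filtering stage.
#' @param bandpass passband used when `bandlimit = TRUE`.
#' @return list with elements `manifest` (tibble: subject_id, group,
#'   true_coupling, camcog_total, praxis, max_translation_mm,
#'   max_rotation_deg), `series` (named list of [time_series_matrix()]), and
#'   `modules` (the module assignment).
#' @export
generate_cohort <- function(spec = cohort_spec(), bandlimit = TRUE,
                            bandpass = bandpass_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  modules <- module_assignment(spec$n_regions, spec$n_modules)
  region_ids <- paste0("R", seq_len(spec$n_regions))
  groups <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  ids <- c(sprintf("pat%02d", seq_len(spec$n_patients)),
           sprintf("con%02d", seq_len(spec$n_controls)))
  targets <- ifelse(groups == "patient", spec$within_r_patient,
                    spec$within_r_control)

  series <- vector("list", length(ids))
  names(series) <- ids
  rows <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    coupling <- rtruncnorm1(targets[s], spec$coupling_sd,
                            spec$between_r, 0.95)
    sigma <- block_correlation_matrix(spec$n_regions, modules,
                                      coupling, spec$between_r)
    z <- matrix(rnorm(spec$n_timepoints * spec$n_regions),
                spec$n_timepoints, spec$n_regions) %*% chol(sigma)
    x <- t(z) + spec$noise_sd *
      matrix(rnorm(spec$n_regions * spec$n_timepoints),
             spec$n_regions, spec$n_timepoints)
    camcog <- spec$cognition_intercept + spec$cognition_slope * coupling +
      rnorm(1, 0, spec$cognition_sd)
    praxis <- 4.2 + 11 * coupling + rnorm(1, 0, 0.8)
    motion_t <- r_motion()
    motion_r <- r_motion()
    ts <- time_series_matrix(x, subject_id = ids[s],
                             tr_seconds = spec$tr_seconds,
                             region_ids = region_ids)
    series[[s]] <- ts
    rows[[s]] <- tibble::tibble(
      subject_id = ids[s], group = groups[s], true_coupling = coupling,
      camcog_total = camcog, praxis = praxis,
      max_translation_mm = motion_t, max_rotation_deg = motion_r)
  }
  if (bandlimit) {
    series <- lapply(series, bandpass_filter, spec = bandpass)
  }
  manifest <- dplyr::bind_rows(rows)
  list(manifest = manifest, series = series, modules = modules)
}

#' Mean within- and between-module correlation
#'
#' Ground-truth verification helper: the mean of off-diagonal Pearson
#' correlations within covariance blocks versus between them.
#'
#' @param ts a [time_series_matrix()].
#' @param modules module labels covering every region.
#' @return list with `within_r` and `between_r`.
#' @export
empirical_block_correlation <- function(ts, modules) {
  stopifnot(inherits(ts, "time_series_matrix"))
  if (length(modules) != nrow(ts$data))
    stop_fcnet("module labels (%d) do not cover all %d regions",
               length(modules), nrow(ts$data))
  if (!any(table(modules) >= 2))
    stop_fcnet("within-module correlation undefined: every block has < 2 regions")
  r <- cor(t(ts$data))
  same <- outer(modules, modules, "==")
  ut <- upper.tri(r)
  list(within_r = mean(r[ut & same]), between_r = mean(r[ut & !same]))
}
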