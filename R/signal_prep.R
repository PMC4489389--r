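#' Band-pass specification
#'
#' The passband applied to regional BOLD series before connectivity is
#' estimated. The conventional resting-state band 0.01-0.08 Hz removes
#' scanner drift below and respiratory/cardiac noise above.
#'
#' @param f_low lower edge in Hz.
#' @param f_high upper edge in Hz; must stay below the Nyquist frequency
#'   `1 / (2 * tr_seconds)` of the series it is applied to.
#' @return an object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(f_low = 0.01, f_high = 0.08) {
  if (!(f_low > 0)) stop_fcnet("f_low must be > 0 (got %g)", f_low)
  if (!(f_high > f_low)) stop_fcnet("f_high (%g) must exceed f_low (%g)",
                                    f_high, f_low)
  structure(list(f_low = f_low, f_high = f_high), class = "bandpass_spec")
}

#' Motion exclusion rule
#'
#' Subjects whose head motion *exceeds* either bound in any direction are
#' excluded; the comparison is a strict inequality, so a subject exactly at
#' the bound is kept.
#'
#' @param max_translation_mm translation bound in millimetres.
#' @param max_rotation_deg rotation bound in degrees.
#' @return an object of class `motion_rule`.
#' @export
motion_rule <- function(max_translation_mm = 3.0, max_rotation_deg = 3.0) {
  if (max_translation_mm <= 0 || max_rotation_deg <= 0)
    stop_fcnet("motion bounds must be positive")
  structure(list(max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg), class = "motion_rule")
}

# Butterworth band-pass coefficients for a given sampling interval.
butter_coefs <- function(spec, tr_seconds, order = 4) {
  nyq <- 1 / (2 * tr_seconds)
  if (spec$f_high >= nyq)
    stop_fcnet("f_high (%g Hz) must be below the Nyquist frequency (%g Hz)",
               spec$f_high, nyq)
  signal::butter(order, c(spec$f_low, spec$f_high) / nyq, type = "pass")
}

# Settling length of an ARMA filter: samples until the slowest pole's impulse
# response decays below 1%. Used as the reflection-padding length.
filter_settle_length <- function(coefs) {
  p <- tryCatch(Mod(polyroot(rev(coefs$a))), error = function(e) numeric(0))
  p <- p[is.finite(p) & p < 1]
  base_len <- 3 * (max(length(coefs$a), length(coefs$b)) - 1)
  if (length(p) == 0) return(base_len)
  max(base_len, ceiling(log(0.01) / log(max(p))))
}

# Zero-phase forward-backward pass of one series with symmetric-reflection
# padding. Symmetric (not sign-flipped) reflection keeps the padding inside
# the signal's own range, so no step is introduced at the junctions; a step
# would excite the filter's slow poles and leak transients into the series.
filtfilt_padded <- function(coefs, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  left <- x[(pad + 1):2]
  right <- x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(coefs$b, coefs$a, xp)
  y <- rev(signal::filter(coefs$b, coefs$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Temporal band-pass filtering of regional time series
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to every
#' region's series. Each series is demeaned before filtering and after, so
#' the DC component is removed exactly; edge transients are suppressed by
#' odd-reflection padding of one filter-settling length. The zero-phase pass
#' avoids introducing lags that would distort zero-lag Pearson correlations.
#'
#' @param ts a [time_series_matrix()].
#' @param spec a [bandpass_spec()]; default passband 0.01-0.08 Hz.
#' @param order Butterworth design order (the zero-phase pass doubles the
#'   effective roll-off).
#' @return a filtered [time_series_matrix()] of the same shape.
#' @export
bandpass_filter <- function(ts, spec = bandpass_spec(), order = 4) {
  stopifnot(inherits(ts, "time_series_matrix"))
  if (!inherits(spec, "bandpass_spec")) stop_fcnet("spec must be a bandpass_spec")
  coefs <- butter_coefs(spec, ts$tr_seconds, order)
  flen <- max(length(coefs$a), length(coefs$b)) - 1
  n_t <- ncol(ts$data)
  if (n_t < 3 * flen)
    stop_fcnet("series too short for stable filtering: %d timepoints < 3 x filter order (%d)",
               n_t, flen)
  pad <- filter_settle_length(coefs)
  out <- ts$data
  for (i in seq_len(nrow(out))) {
    x <- out[i, ] - mean(out[i, ])
    y <- filtfilt_padded(coefs, x, pad)
    out[i, ] <- y - mean(y)
  }
  time_series_matrix(out, subject_id = ts$subject_id,
                     tr_seconds = ts$tr_seconds, region_ids = ts$region_ids)
}

#' Motion-based quality control
#'
#' Splits a cohort into kept and excluded subjects. A subject is excluded if
#' and only if their maximum translation strictly exceeds the translation
#' bound or their maximum rotation strictly exceeds the rotation bound.
#'
#' @param manifest cohort manifest with columns `subject_id`,
#'   `max_translation_mm`, `max_rotation_deg`.
#' @param rule a [motion_rule()].
#' @return list with character vectors `kept` and `excluded` (disjoint,
#'   jointly covering all subjects).
#' @export
apply_motion_qc <- function(manifest, rule = motion_rule()) {
  req <- c("subject_id", "max_translation_mm", "max_rotation_deg")
  miss <- setdiff(req, names(manifest))
  if (length(miss) > 0)
    stop_fcnet("manifest lacks motion columns: %s", paste(miss, collapse = ", "))
  bad <- !is.finite(manifest$max_translation_mm) |
    !is.finite(manifest$max_rotation_deg)
  if (any(bad))
    stop_fcnet("missing motion summary for subject(s): %s",
               paste(manifest$subject_id[bad], collapse = ", "))
  out <- manifest$max_translation_mm > rule$max_translation_mm |
    manifest$max_rotation_deg > rule$max_rotation_deg
  list(kept = manifest$subject_id[!out], excluded = manifest$subject_id[out])
}

#' Discard initial volumes
#'
#' Removes the first `n_discard` timepoints of a series, the conventional
#' guard against T1-equilibration transients at the start of a scan.
#'
#' @param ts a [time_series_matrix()].
#' @param n_discard number of leading timepoints to drop (default 10).
#' @return a shortened [time_series_matrix()].
#' @export
discard_initial_volumes <- function(ts, n_discard = 10) {
  stopifnot(inherits(ts, "time_series_matrix"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) stop_fcnet("n_discard must be non-negative")
  if (n_discard >= ncol(ts$data))
    stop_fcnet("cannot discard %d of %d timepoints", n_discard, ncol(ts$data))
  if (n_discard == 0) return(ts)
  time_series_matrix(ts$data[, -seq_len(n_discard), drop = FALSE],
                     subject_id = ts$subject_id, tr_seconds = ts$tr_seconds,
                     region_ids = ts$region_ids)
}
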