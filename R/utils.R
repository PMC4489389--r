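# Internal helpers shared across modules.

# round-half-away-from-zero; base round() is banker's and would change the
# edge count K for sparsities landing exactly on .5
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive a reproducible sub-seed from a base seed and labels
#'
#' Stable 31-bit integer derived from a base seed plus arbitrary labels
#' (e.g. subject id and sparsity), so per-unit random ensembles are
#' reproducible and independent of execution order.
#'
#' @param seed base integer seed.
#' @param ... labels (coerced to character) mixed into the hash.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (part in list(...)) {
    for (b in utf8ToInt(paste0(format(part, digits = 12), "|"))) {
      h <- (h * 131 + b) %% 2147483647
    }
  }
  as.integer(h)
}

# FNV-1a over a character scalar, reported as hex; used to fingerprint configs
# in run logs.
fnv1a_hash <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stop_fcnet <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric membership with tolerance, returning match indices or NA
match_num <- function(x, table, tol = 1e-8) {
  vapply(x, function(xi) {
    i <- which(abs(table - xi) < tol)
    if (length(i) == 0L) NA_integer_ else i[1L]
  }, integer(1))
}
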