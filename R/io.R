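# Tabular IO. All tables are TSV with a header row, UTF-8, '.' decimal.
# Region indexing is 1-based in files (atlas convention); in-memory objects
# use region label strings.

# %.17g guarantees the printed decimal text parses back to the identical
# double, making write-then-read an exact identity on values
fmt17 <- function(x) sub("^-0$", "0", sprintf("%.17g", x))

#' Read the bundled 90-region atlas table
#'
#' Cortical/subcortical parcellation labels (index, name, abbreviation,
#' hemisphere) in standard atlas numbering, used to validate region order
#' and to name regions in reports.
#'
#' @param path TSV path; default is the table shipped with the package.
#' @return tibble with columns `index`, `name`, `abbreviation`, `hemisphere`.
#' @export
read_region_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "aal90_regions.tsv",
                                package = "fcnet", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("index", "name", "abbreviation", "hemisphere")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop_fcnet("region table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$index) ||
      !identical(as.integer(sort(tab$index)), seq_len(nrow(tab))))
    stop_fcnet("region indices must be unique and contiguous from 1")
  tab
}

#' Write / read a subject's time series as TSV
#'
#' Layout: first column `region` (1-based region index), remaining columns
#' the timepoint indices `1..T`.
#'
#' @param ts a [time_series_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(ts, path) {
  stopifnot(inherits(ts, "time_series_matrix"))
  chr <- matrix(fmt17(ts$data), nrow = nrow(ts$data))
  tab <- tibble::as_tibble(chr, .name_repair = ~ as.character(
    seq_len(ncol(ts$data))))
  tab <- dplyr::bind_cols(tibble::tibble(region = seq_len(nrow(ts$data))), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_time_series
#' @param subject_id identifier for the loaded subject; default: file stem.
#' @param tr_seconds sampling interval of the stored series.
#' @param region_table optional [read_region_table()] output; if given, the
#'   file's region count and indices are validated against it.
#' @export
read_time_series <- function(path, subject_id = NULL, tr_seconds = 2.0,
                             region_table = NULL) {
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  # base read.delim: strtod parsing is correctly rounded, so values are
  # recovered exactly as written
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"region" %in% names(tab))
    stop_fcnet("%s: missing 'region' column", path)
  m <- suppressWarnings(
    vapply(tab[setdiff(names(tab), "region")], as.numeric,
           numeric(nrow(tab))))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(tab))
  if (anyNA(m) || any(is.infinite(m))) {
    bad <- which(apply(is.na(m) | is.infinite(m), 1, any))[1]
    stop_fcnet("%s: non-numeric or missing cell at data line %d", path,
               bad + 1)
  }
  tab$region <- suppressWarnings(as.integer(tab$region))
  if (anyNA(tab$region))
    stop_fcnet("%s: non-integer region index", path)
  region_ids <- paste0("R", tab$region)
  if (!is.null(region_table)) {
    if (nrow(tab) != nrow(region_table))
      stop_fcnet("%s: region mismatch: file has %d regions, table has %d",
                 path, nrow(tab), nrow(region_table))
    if (!identical(as.integer(tab$region), as.integer(region_table$index)))
      stop_fcnet("%s: region indices do not match the region table", path)
    region_ids <- region_table$abbreviation
  }
  time_series_matrix(m, subject_id = subject_id, tr_seconds = tr_seconds,
                     region_ids = region_ids)
}

#' Write / read a square matrix (connectivity or adjacency) as TSV
#'
#' Region identifiers form both the header row and the first column.
#'
#' @param m square matrix with region dimnames.
#' @param path output file.
#' @return `path` invisibly (writer); the matrix (reader).
#' @export
write_square_matrix <- function(m, path) {
  chr <- matrix(fmt17(m), nrow = nrow(m), dimnames = dimnames(m))
  tab <- tibble::as_tibble(chr, rownames = "region")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_square_matrix
#' @export
read_square_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  m <- vapply(tab[-1], as.numeric, numeric(nrow(tab)))
  rownames(m) <- tab[[1]]
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop_fcnet("%s: not a square region x region table", path)
  m
}

#' Write / read a cohort manifest as TSV
#'
#' @param manifest manifest tibble (see [generate_cohort()]).
#' @param path file path.
#' @return `path` invisibly (writer); the manifest tibble (reader).
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("subject_id", "group") %in% names(tab)))
    stop_fcnet("%s: manifest needs subject_id and group columns", path)
  if (anyDuplicated(tab$subject_id))
    stop_fcnet("%s: duplicate subject ids", path)
  tab
}

#' Published cohort demographic summary table
#'
#' The printed demographic and neuropsychological summary statistics
#' (mean, SD, n per group, plus the printed p-value) of the SVCI
#' case-control cohort whose design the synthetic generator emulates.
#' Used to validate [summary_ttest()] against published values.
#'
#' @return tibble with columns `variable`, `patient_mean`, `patient_sd`,
#'   `patient_n`, `control_mean`, `control_sd`, `control_n`, `printed_p`,
#'   `reproducible` (whether the printed p is recoverable from the printed
#'   triples; a few published rows are internally inconsistent).
#' @export
read_cohort_summary <- function() {
  path <- system.file("extdata", "svci_cohort_summary.tsv",
                      package = "fcnet", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Pooled t-tests over a summary-statistics table
#'
#' Applies [summary_ttest()] to each row of a (mean, SD, n) summary table
#' such as [read_cohort_summary()].
#'
#' @param tbl summary table in the [read_cohort_summary()] layout.
#' @return the table with `t`, `df`, `p` and `p_3dp` columns appended.
#' @export
cohort_summary_tests <- function(tbl) {
  res <- mapply(function(m1, s1, n1, m2, s2, n2)
    summary_ttest(m1, s1, n1, m2, s2, n2),
    tbl$patient_mean, tbl$patient_sd, tbl$patient_n,
    tbl$control_mean, tbl$control_sd, tbl$control_n, SIMPLIFY = FALSE)
  tbl |>
    dplyr::mutate(t = vapply(res, `[[`, numeric(1), "t"),
                  df = vapply(res, `[[`, numeric(1), "df"),
                  p = vapply(res, `[[`, numeric(1), "p"),
                  p_3dp = round(.data$p, 3))
}
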