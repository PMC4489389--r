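#' Pipeline configuration
#'
#' Bundles every stage's options into one round-trippable object. The
#' `cohort` element is a [cohort_spec()] (synthetic source) or a list with
#' `manifest` and `series_dir` paths (ingestion source).
#'
#' @param cohort a [cohort_spec()] or list of input paths.
#' @param bandpass a [bandpass_spec()].
#' @param motion a [motion_rule()].
#' @param grid a [sparsity_grid()].
#' @param nulls a [null_ensemble_spec()]; `n_random = 0` disables the
#'   small-world stage.
#' @param edge_sign edge ranking convention, see [threshold_by_sparsity()].
#' @param fdr_q,report_sparsity,auc_range statistics options, see
#'   [compare_groups_over_grid()].
#' @param correlation_range AUC range for cognition correlations.
#' @param correlation_group which group to correlate (default `"patient"`).
#' @param score_cols cognitive score columns in the manifest.
#' @param seed master seed for the run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            bandpass = bandpass_spec(),
                            motion = motion_rule(),
                            grid = sparsity_grid(),
                            nulls = null_ensemble_spec(),
                            edge_sign = "positive",
                            fdr_q = 0.05, report_sparsity = 0.18,
                            auc_range = NULL,
                            correlation_range = c(0.08, 0.31),
                            correlation_group = "patient",
                            score_cols = c("camcog_total", "praxis"),
                            seed = 1L) {
  structure(list(cohort = cohort, bandpass = bandpass, motion = motion,
                 grid = grid, nulls = nulls, edge_sign = edge_sign,
                 fdr_q = fdr_q, report_sparsity = report_sparsity,
                 auc_range = auc_range,
                 correlation_range = correlation_range,
                 correlation_group = correlation_group,
                 score_cols = score_cols, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(x))`
#' reconstructs an identical configuration.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); a [pipeline_config()] (reader).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- if (!is.null(raw$cohort$n_patients))
    do.call(cohort_spec, raw$cohort) else raw$cohort
  pipeline_config(
    cohort = cohort,
    bandpass = do.call(bandpass_spec, raw$bandpass),
    motion = do.call(motion_rule, raw$motion),
    grid = sparsity_grid(raw$grid$s_min, raw$grid$s_max, raw$grid$step),
    nulls = do.call(null_ensemble_spec, raw$nulls),
    edge_sign = raw$edge_sign, fdr_q = raw$fdr_q,
    report_sparsity = raw$report_sparsity,
    auc_range = if (is.null(raw$auc_range)) NULL else unlist(raw$auc_range),
    correlation_range = unlist(raw$correlation_range),
    correlation_group = raw$correlation_group,
    score_cols = unlist(raw$score_cols), seed = raw$seed)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_fcnet("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Cohort generation (or ingestion) -> motion QC -> band-pass filtering ->
#' correlation connectomes -> binary network families -> metric curves ->
#' small-world normalization -> group statistics -> cognition correlations.
#' All result tables are written as TSV under `out_dir` together with a run
#' log (seed, config hash, per-stage record counts). Reruns with the same
#' config and seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param include_nodal carry nodal curves through metrics and statistics.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main in-memory results and the output
#'   paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         include_nodal = TRUE, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  log_lines <- c(sprintf("fcnet run, seed %d", config$seed),
                 sprintf("config hash: %s", pipeline_config_hash(config)))

  # cohort: synthetic (unfiltered; filtering is its own stage) or from disk
  cohort <- stage("simulate", {
    if (inherits(config$cohort, "cohort_spec")) {
      spec <- config$cohort
      spec$seed <- derive_seed(config$seed, "cohort")
      generate_cohort(spec, bandlimit = FALSE)
    } else {
      manifest <- read_manifest(config$cohort$manifest)
      series <- lapply(manifest$subject_id, function(id)
        read_time_series(file.path(config$cohort$series_dir,
                                   paste0(id, ".tsv")), subject_id = id))
      names(series) <- manifest$subject_id
      list(manifest = manifest, series = series, modules = NULL)
    }
  })
  write_manifest(cohort$manifest, file.path(out_dir, "manifest.tsv"))
  log_lines <- c(log_lines, sprintf("subjects simulated/loaded: %d",
                                    nrow(cohort$manifest)))
  say("cohort: %d subjects", nrow(cohort$manifest))

  qc <- stage("qc", apply_motion_qc(cohort$manifest, config$motion))
  readr::write_tsv(tibble::tibble(
    subject_id = c(qc$kept, qc$excluded),
    status = rep(c("kept", "excluded"), c(length(qc$kept),
                                          length(qc$excluded)))),
    file.path(out_dir, "qc.tsv"), progress = FALSE)
  manifest <- cohort$manifest[cohort$manifest$subject_id %in% qc$kept, ]
  series <- cohort$series[qc$kept]
  log_lines <- c(log_lines, sprintf("qc: kept %d, excluded %d",
                                    length(qc$kept), length(qc$excluded)))
  say("qc: excluded %d subject(s)", length(qc$excluded))

  series <- stage("filter", lapply(series, bandpass_filter,
                                   spec = config$bandpass))

  curves <- stage("metrics", {
    res <- lapply(series, function(ts) {
      cm <- correlation_matrix(ts)
      fam <- build_network_family(cm, config$grid,
                                  edge_sign = config$edge_sign)
      compute_metric_curves(fam, config$grid, include_nodal = include_nodal)
    })
    list(global = dplyr::bind_rows(lapply(res, `[[`, "global")),
         nodal = if (include_nodal)
           dplyr::bind_rows(lapply(res, `[[`, "nodal")) else NULL,
         unreachable = dplyr::bind_rows(lapply(res, `[[`, "unreachable")))
  })
  readr::write_tsv(curves$global, file.path(out_dir, "metric_curves.tsv"),
                   progress = FALSE)
  if (include_nodal)
    readr::write_tsv(curves$nodal, file.path(out_dir, "nodal_curves.tsv"),
                     progress = FALSE)
  log_lines <- c(log_lines, sprintf("metric curve rows: %d",
                                    nrow(curves$global)))
  say("metrics: %d global curve rows", nrow(curves$global))

  sw <- NULL
  if (config$nulls$n_random > 0) {
    sw <- stage("nulls", {
      rows <- list()
      for (id in manifest$subject_id) {
        ts_net <- build_network_family(
          correlation_matrix(series[[id]]), config$grid,
          edge_sign = config$edge_sign)
        for (g in ts_net) {
          spec_i <- config$nulls
          spec_i$seed <- derive_seed(config$seed, "nulls", id, g$sparsity)
          idx <- small_world_indices(g, spec_i)
          rows[[length(rows) + 1]] <- tibble::tibble(
            subject_id = id,
            group = manifest$group[manifest$subject_id == id],
            sparsity = g$sparsity, gamma = idx$gamma, lambda = idx$lambda,
            sigma = idx$sigma, cp_random_mean = idx$cp_random_mean,
            cp_random_sd = idx$cp_random_sd,
            lp_random_mean = idx$lp_random_mean,
            lp_random_sd = idx$lp_random_sd)
        }
      }
      dplyr::bind_rows(rows)
    })
    readr::write_tsv(sw, file.path(out_dir, "small_world.tsv"),
                     progress = FALSE)
    log_lines <- c(log_lines, sprintf("small-world rows: %d", nrow(sw)))
    say("nulls: %d subject x sparsity rows", nrow(sw))
  }

  single_threshold <- length(config$grid$values) < 2
  tests <- stage("compare", {
    if (single_threshold) {
      warning("single-threshold grid: AUC comparison skipped", call. = FALSE)
      compare_groups_over_grid(
        curves$global, manifest, config$grid,
        nodal_curves = curves$nodal, fdr_q = config$fdr_q,
        report_sparsity = config$grid$values[1], auc = FALSE)
    } else {
      compare_groups_over_grid(
        curves$global, manifest, config$grid, nodal_curves = curves$nodal,
        fdr_q = config$fdr_q, report_sparsity = config$report_sparsity,
        auc_range = config$auc_range)
    }
  })
  readr::write_tsv(tests, file.path(out_dir, "group_tests.tsv"),
                   progress = FALSE)
  log_lines <- c(log_lines, sprintf("group test rows: %d", nrow(tests)))

  cors <- NULL
  if (!single_threshold &&
      all(config$score_cols %in% names(manifest))) {
    cors <- stage("correlate", {
      keep <- manifest$subject_id[manifest$group %in%
                                    config$correlation_group]
      metric_cognition_correlation(
        dplyr::filter(curves$global, .data$subject_id %in% keep),
        manifest, config$score_cols, range = config$correlation_range,
        nodal_curves = if (include_nodal)
          dplyr::filter(curves$nodal, .data$subject_id %in% keep)
        else NULL)
    })
    readr::write_tsv(cors, file.path(out_dir, "correlations.tsv"),
                     progress = FALSE)
    log_lines <- c(log_lines, sprintf("correlation rows: %d", nrow(cors)))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  writeLines(pipeline_summary(manifest, curves, sw, tests, cors),
             file.path(out_dir, "summary.txt"))
  invisible(list(manifest = manifest, qc = qc, curves = curves,
                 small_world = sw, tests = tests, correlations = cors,
                 out_dir = out_dir))
}

#' @rdname write_pipeline_config
#' @export
pipeline_config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  fnv1a_hash(paste(readLines(tmp), collapse = "\n"))
}

pipeline_summary <- function(manifest, curves, sw, tests, cors) {
  lines <- c("fcnet pipeline summary", "======================",
             sprintf("subjects analysed: %d (%d patients, %d controls)",
                     nrow(manifest), sum(manifest$group == "patient"),
                     sum(manifest$group == "control")))
  sig <- tests[tests$comparison == "auc" & tests$significant, ]
  if (nrow(sig) > 0) {
    lines <- c(lines, "significant AUC group differences (q < threshold):",
               sprintf("  %s: t = %.3f, q = %.4f, %s in patients",
                       sig$metric, sig$t, sig$q,
                       ifelse(sig$direction > 0, "higher", "lower")))
  } else {
    lines <- c(lines, "no significant AUC group differences")
  }
  if (!is.null(cors)) {
    gsig <- cors[cors$scope == "global" & cors$q < 0.05, ]
    if (nrow(gsig) > 0)
      lines <- c(lines, "global metric-cognition correlations (q < 0.05):",
                 sprintf("  %s ~ %s: r = %.3f, p = %.4f",
                         gsig$metric, gsig$score, gsig$r, gsig$p))
  }
  lines
}
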