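# End-to-end orchestration: simulate (or load) -> probe stats -> promoter
# calls -> genomic clustering -> CpG density contrasts -> summary, with a run
# manifest recording config, seeds, file digests and timings so identical
# inputs reproduce identical outputs.

#' Run the full analysis pipeline
#'
#' Either simulates inputs from `sim_config` or loads them from
#' `input_dir` (files as written by [write_annotation()] and
#' [write_matrix()]). All stage outputs are written under `out_dir` as TSV,
#' plus `summary.tsv` with the headline counts and `manifest.json` with the
#' config snapshot, seed, output digests and stage timings.
#'
#' @param out_dir Output directory (created).
#' @param config An [analysis_config()].
#' @param sim_config A [synthetic_config()]; used when `input_dir` is NULL.
#' @param input_dir Optional directory holding `probes.bed`,
#'   `promoters.tsv`, `chrom.sizes`, `matrix.tsv`, `design.tsv`.
#' @param run_distance_correlation Compute the (comparatively expensive)
#'   distance-correlation stage. Default TRUE.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(out_dir,
                         config = analysis_config(),
                         sim_config = synthetic_config(seed = config$seed),
                         input_dir = NULL,
                         run_distance_correlation = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  if (is.null(input_dir)) {
    message("simulating inputs (seed ", sim_config$seed, ")")
    annotation <- clock("simulate_annotation", generate_annotation(sim_config))
    sim <- clock("simulate_matrix", generate_matrix(sim_config, annotation))
    mat <- sim$matrix
    truth <- sim$truth
    write_annotation(annotation, out_dir)
    write_matrix(mat, out_dir)
    write_results(truth, file.path(out_dir, "truth.tsv"))
  } else {
    annotation <- read_annotation(file.path(input_dir, "probes.bed"),
                                  file.path(input_dir, "promoters.tsv"),
                                  file.path(input_dir, "chrom.sizes"))
    mat <- read_matrix(file.path(input_dir, "matrix.tsv"),
                       file.path(input_dir, "design.tsv"))
    truth <- NULL
  }

  probe_res <- clock("probe_stats", probe_stats(mat, config))
  write_results(probe_res, file.path(out_dir, "probe_results.tsv"))
  message(sum(probe_res$probe_call != "none"), " / ", nrow(probe_res),
          " probes pass the probe-level criteria")

  prom_res <- clock("promoter_stats",
                    promoter_stats(probe_res, annotation, config))
  write_results(prom_res, file.path(out_dir, "promoter_results.tsv"))
  n_up <- sum(prom_res$dm_call & prom_res$direction == "up_in_cpa")
  n_down <- sum(prom_res$dm_call & prom_res$direction == "down_in_cpa")
  message(sum(prom_res$dm_call), " promoters called (", n_up, " up, ",
          n_down, " down in CPA)")

  chrom_enr <- if (sum(prom_res$dm_call) > 0) {
    clock("chromosome_enrichment",
          chromosome_enrichment(prom_res, annotation))
  } else NULL
  if (!is.null(chrom_enr)) {
    write_results(chrom_enr, file.path(out_dir, "chromosome_enrichment.tsv"))
  }

  windows <- clock("window_scan", window_scan(probe_res, annotation, config))
  write_results(windows, file.path(out_dir, "window_scan.tsv"))
  enr_win <- enriched_windows(windows, config$promoter_fdr_threshold)
  write_results(enr_win, file.path(out_dir, "enriched_windows.tsv"))
  message(nrow(enr_win), " enriched window(s) at FDR <= ",
          config$promoter_fdr_threshold)

  dist_corr <- if (run_distance_correlation) {
    clock("distance_correlation",
          distance_correlation(probe_res, annotation, config))
  } else NULL
  if (!is.null(dist_corr)) {
    write_results(dist_corr, file.path(out_dir, "distance_correlation.tsv"))
  }

  density <- promoter_cpg_density(annotation)
  density_contrasts <- if (n_up >= 2 && n_down >= 2) {
    clock("cpg_density", compare_density_groups(density, prom_res))
  } else NULL
  if (!is.null(density_contrasts)) {
    write_results(density_contrasts, file.path(out_dir,
                                               "density_contrasts.tsv"))
  }

  summary_tab <- data.frame(
    quantity = c("n_probes", "n_probe_calls", "n_promoters",
                 "n_dm_promoters", "n_dm_up_in_cpa", "n_dm_down_in_cpa",
                 "n_strict_promoters", "n_enriched_windows"),
    value = c(nrow(probe_res), sum(probe_res$probe_call != "none"),
              nrow(prom_res), sum(prom_res$dm_call), n_up, n_down,
              sum(prom_res$strict_call), nrow(enr_win))
  )
  write_results(summary_tab, file.path(out_dir, "summary.tsv"))

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("medipscan")),
    seed = config$seed,
    analysis_config = unclass(config),
    synthetic_config = if (is.null(input_dir)) unclass(sim_config) else NULL,
    input_dir = input_dir,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)),
    timings_sec = as.list(timings)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(annotation = annotation, matrix = mat, truth = truth,
                 probe_results = probe_res, promoter_results = prom_res,
                 chromosome_enrichment = chrom_enr, windows = windows,
                 enriched_windows = enr_win,
                 distance_correlation = dist_corr,
                 density_contrasts = density_contrasts,
                 summary = summary_tab, manifest = manifest))
}

#' Score recovery of planted effects
#'
#' Compares promoter calls against a generator truth table: sensitivity
#' (planted promoters called in any direction), false discovery proportion
#' among calls, and direction accuracy among true positives.
#'
#' @param promoter_results Output of [call_promoters()].
#' @param truth Truth table from [generate_matrix()].
#' @return list: `sensitivity`, `fdp`, `direction_accuracy`, `n_called`,
#'   `n_planted`.
#' @export
score_recovery <- function(promoter_results, truth) {
  m <- merge(promoter_results, truth, by = "promoter_id",
             suffixes = c("", ".truth"))
  called <- m$dm_call
  planted <- m$planted
  tp <- called & planted
  list(
    sensitivity = if (sum(planted) > 0) sum(tp) / sum(planted) else NA_real_,
    fdp = if (sum(called) > 0) sum(called & !planted) / sum(called) else 0,
    direction_accuracy = if (sum(tp) > 0) {
      mean(m$direction[tp] == m$direction.truth[tp])
    } else NA_real_,
    n_called = sum(called),
    n_planted = sum(planted)
  )
}
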