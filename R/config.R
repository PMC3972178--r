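# Analysis configuration: thresholds and scan parameters shared by all stages.

#' Analysis configuration
#'
#' Bundles the thresholds and scan parameters used across the pipeline:
#' probe-level call criteria, promoter-level FDR cutoffs, the genomic window
#' size for the enrichment scan, and the distance-correlation settings.
#'
#' @param probe_p_threshold Maximum (uncorrected) probe t-test p-value for a
#'   probe to be called differentially methylated. Default 0.05.
#' @param min_abs_log2fc Minimum absolute log2 fold difference (CPA minus
#'   control group mean) for a probe call. Default 0.25.
#' @param promoter_fdr_threshold Maximum Benjamini-Hochberg FDR of the
#'   promoter-level rank-sum statistic for a differential-methylation call.
#'   Default 0.2.
#' @param strict_fdr_threshold Secondary, stricter FDR cutoff reported
#'   alongside the main call. Default 0.05.
#' @param window_size Width in bp of the non-overlapping genomic windows used
#'   by [window_scan()]. Default 500000 (500 kb).
#' @param max_correlation_distance Largest probe-pair separation in bp
#'   considered by [distance_correlation()]. Default 1e7.
#' @param distance_bin_width Width in bp of the distance bins for
#'   [distance_correlation()]. Default 500000.
#' @param permutations Number of position permutations used for the
#'   distance-correlation null envelope. Default 200.
#' @param pair_cap Maximum number of probe pairs retained per distance bin
#'   (uniform seeded subsampling above this). Default 2e6.
#' @param fdr_direction_pooling How the two one-sided promoter p-values enter
#'   the BH adjustment: `"pooled"` adjusts the per-promoter minimum directly
#'   (one FDR column per promoter); `"bonferroni"` doubles the minimum first.
#' @param seed Integer seed from which all stochastic stages derive their
#'   sub-seeds.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(probe_p_threshold = 0.05,
                            min_abs_log2fc = 0.25,
                            promoter_fdr_threshold = 0.2,
                            strict_fdr_threshold = 0.05,
                            window_size = 500000,
                            max_correlation_distance = 1e7,
                            distance_bin_width = 500000,
                            permutations = 200,
                            pair_cap = 2e6,
                            fdr_direction_pooling = c("pooled", "bonferroni"),
                            seed = 1L) {
  fdr_direction_pooling <- match.arg(fdr_direction_pooling)
  cfg <- list(
    probe_p_threshold = probe_p_threshold,
    min_abs_log2fc = min_abs_log2fc,
    promoter_fdr_threshold = promoter_fdr_threshold,
    strict_fdr_threshold = strict_fdr_threshold,
    window_size = window_size,
    max_correlation_distance = max_correlation_distance,
    distance_bin_width = distance_bin_width,
    permutations = permutations,
    pair_cap = pair_cap,
    fdr_direction_pooling = fdr_direction_pooling,
    seed = as.integer(seed)
  )
  validate_analysis_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_analysis_config <- function(cfg) {
  for (nm in c("probe_p_threshold", "promoter_fdr_threshold",
               "strict_fdr_threshold")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop(sprintf("'%s' must be a single probability in (0, 1]", nm),
           call. = FALSE)
    }
  }
  if (cfg$min_abs_log2fc < 0) stop("'min_abs_log2fc' must be >= 0", call. = FALSE)
  for (nm in c("window_size", "max_correlation_distance",
               "distance_bin_width", "pair_cap")) {
    if (cfg[[nm]] <= 0) stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
  }
  if (cfg$permutations < 1) stop("'permutations' must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read an analysis configuration from JSON or YAML
#'
#' Fields not present in the file keep their [analysis_config()] defaults;
#' unknown fields are an error.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `analysis_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format '.", ext, "' (use JSON or YAML)",
         call. = FALSE)
  )
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

# Deterministic sub-seed for a named stage, so one run seed fans out to
# independent per-stage RNG streams. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
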