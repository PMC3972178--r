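# Promoter-level aggregation: each promoter is tested for enrichment of its
# probes' moderated t-statistics relative to all other probes on the array
# (rank-sum in both directions), followed by Benjamini-Hochberg FDR across
# promoters and the joint probe+promoter differential-methylation call.

#' Promoter-level rank-sum enrichment
#'
#' For every promoter, the moderated t-statistics of its probes are compared
#' against those of all other probes on the array by the Wilcoxon rank-sum
#' test, one-sided in each direction. Because the combined sample in each
#' test is the full array, ranks are computed once globally (midranks) and
#' each promoter's rank sum is read off them. `p_up` tests enrichment with
#' positive t (more methylated in CPA), `p_down` with negative t; the
#' promoter direction is the smaller side and `promoter_p = min(p_up,
#' p_down)`.
#'
#' @param probe_results Output of [moderated_t()] / [probe_stats()].
#' @param annotation A `medip_annotation` covering all probes.
#' @return data.frame: `promoter_id`, `gene_symbol`, `n_probes`, `p_up`,
#'   `p_down`, `direction`, `promoter_p`. Promoters with zero probes are
#'   excluded with a warning.
#' @export
promoter_enrichment <- function(probe_results, annotation) {
  stopifnot(inherits(annotation, "medip_annotation"))
  idx <- match(probe_results$probe_id, annotation$probes$probe_id)
  if (anyNA(idx)) {
    stop("probe(s) missing from annotation: ",
         paste(utils::head(probe_results$probe_id[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  }
  prom_ids <- annotation$probes$promoter_id[idx]
  tstat <- probe_results$moderated_t
  N <- length(tstat)

  prom_levels <- annotation$promoters$promoter_id
  f <- factor(prom_ids, levels = prom_levels)
  n_probes <- as.integer(table(f))
  empty <- n_probes == 0
  if (any(empty)) {
    warning(sum(empty), " promoter(s) without probes excluded", call. = FALSE)
  }
  if (any(n_probes >= N)) {
    stop("degenerate background: a single promoter holds every probe",
         call. = FALSE)
  }

  r <- rank(tstat)  # midranks over the whole array = combined-sample ranks
  rank_sums <- as.numeric(tapply(r, f, sum))  # level order, NA when empty
  keep <- which(!empty)
  k <- n_probes[keep]
  U <- rank_sums[keep] - k * (k + 1) / 2
  ties <- tie_term(tstat)
  exact_ok <- N <= 25 && ties == 0
  p_up <- ranksum_p(U, k, N - k, ties = ties, exact = exact_ok,
                    alternative = "greater")
  p_down <- ranksum_p(U, k, N - k, ties = ties, exact = exact_ok,
                      alternative = "less")
  data.frame(
    promoter_id = prom_levels[keep],
    gene_symbol = annotation$promoters$gene_symbol[keep],
    n_probes = k,
    p_up = p_up,
    p_down = p_down,
    direction = ifelse(p_up <= p_down, "up_in_cpa", "down_in_cpa"),
    promoter_p = pmin(p_up, p_down),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values: monotone non-decreasing in p, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted values (same length/order).
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] with no NA", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Final promoter differential-methylation calls
#'
#' BH FDR is computed once over all promoters jointly (both directions
#' pooled; switch to Bonferroni-doubled minima via
#' `config$fdr_direction_pooling`). A promoter is called differentially
#' methylated when its FDR is at most `promoter_fdr_threshold` AND at least
#' one of its probes passes the probe-level call in the promoter's
#' direction. `strict_call` marks the subset also passing
#' `strict_fdr_threshold`.
#'
#' @param promoter_results Output of [promoter_enrichment()].
#' @param probe_results Probe results with a `probe_call` column
#'   ([call_probes()]).
#' @param annotation A `medip_annotation` (for the probe-to-promoter map).
#' @param config An [analysis_config()].
#' @return `promoter_results` with added `fdr`, `n_called_probes`, `dm_call`,
#'   `strict_call`, `single_probe` columns.
#' @export
call_promoters <- function(promoter_results, probe_results, annotation,
                           config = analysis_config()) {
  stopifnot("probe_call" %in% names(probe_results))
  p <- promoter_results$promoter_p
  if (config$fdr_direction_pooling == "bonferroni") p <- pmin(2 * p, 1)
  promoter_results$fdr <- bh_fdr(p)

  # count probe calls matching each promoter's direction
  idx <- match(probe_results$probe_id, annotation$probes$probe_id)
  prom_of_probe <- annotation$probes$promoter_id[idx]
  dir_of_prom <- stats::setNames(promoter_results$direction,
                                 promoter_results$promoter_id)
  match_dir <- probe_results$probe_call != "none" &
    probe_results$probe_call == dir_of_prom[prom_of_probe]
  counts <- table(factor(prom_of_probe[match_dir],
                         levels = promoter_results$promoter_id))
  promoter_results$n_called_probes <- as.integer(counts)

  promoter_results$dm_call <-
    promoter_results$fdr <= config$promoter_fdr_threshold &
    promoter_results$n_called_probes >= 1
  promoter_results$strict_call <- promoter_results$dm_call &
    promoter_results$fdr <= config$strict_fdr_threshold
  promoter_results$single_probe <- promoter_results$n_probes == 1
  promoter_results
}

#' Promoter-level pipeline stage
#'
#' Convenience wrapper: enrichment p-values, FDR, calls.
#'
#' @param probe_results Probe results with calls ([probe_stats()]).
#' @param annotation A `medip_annotation`.
#' @param config An [analysis_config()].
#' @return data.frame of per-promoter results with calls.
#' @export
promoter_stats <- function(probe_results, annotation,
                           config = analysis_config()) {
  enr <- promoter_enrichment(probe_results, annotation)
  call_promoters(enr, probe_results, annotation, config)
}
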