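# Spatial structure of differential methylation: per-chromosome
# overrepresentation of called promoters, fixed-window enrichment of called
# probes, and distance-dependent correlation of per-probe group differences.

#' Per-chromosome overrepresentation of differentially methylated promoters
#'
#' One-sided Fisher exact test (hypergeometric upper tail) per chromosome on
#' the 2x2 table \[called on chromosome vs called elsewhere\] x \[promoters on
#' chromosome vs elsewhere\], BH-adjusted across chromosomes. Bar-height
#' representation `-log10(fdr)` is included for plotting.
#'
#' @param promoter_results Output of [call_promoters()] (needs `dm_call`).
#' @param annotation A `medip_annotation`.
#' @return data.frame per chromosome: `chrom`, `n_promoters`, `n_dm`,
#'   `n_dm_elsewhere`, `p`, `fdr`, `neg_log10_fdr`. Chromosomes without
#'   promoters are skipped with a warning.
#' @export
chromosome_enrichment <- function(promoter_results, annotation) {
  stopifnot("dm_call" %in% names(promoter_results))
  total_dm <- sum(promoter_results$dm_call)
  if (total_dm == 0) {
    stop("no differentially methylated promoters; enrichment undefined",
         call. = FALSE)
  }
  chrom_of <- annotation$promoters$chrom[
    match(promoter_results$promoter_id, annotation$promoters$promoter_id)]
  chroms <- names(annotation$chromosome_lengths)
  n_total <- nrow(promoter_results)

  empty <- setdiff(chroms, unique(chrom_of))
  if (length(empty)) {
    warning("chromosome(s) without promoters skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
    chroms <- setdiff(chroms, empty)
  }

  rows <- lapply(chroms, function(ch) {
    on_ch <- chrom_of == ch
    k <- sum(on_ch)                     # promoters drawn from this chromosome
    x <- sum(promoter_results$dm_call & on_ch)
    # upper tail: P(X >= x) with X ~ Hypergeom(total_dm, n_total - total_dm, k)
    p <- stats::phyper(x - 1, total_dm, n_total - total_dm, k,
                       lower.tail = FALSE)
    data.frame(chrom = ch, n_promoters = k, n_dm = x,
               n_dm_elsewhere = total_dm - x, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$neg_log10_fdr <- -log10(out$fdr)
  out
}

#' Fixed-window enrichment scan of differentially methylated probes
#'
#' Chromosomes are partitioned into non-overlapping windows of
#' `config$window_size` bp anchored at coordinate 0. Per window and per call
#' direction, a one-sided Fisher exact test compares the window's fraction of
#' called probes to the rest of the genome; BH adjustment is applied across
#' all windows separately per direction. Probes are assigned to windows by
#' interval midpoint.
#'
#' @param probe_results Probe results with `probe_call` ([call_probes()]).
#' @param annotation A `medip_annotation`.
#' @param config An [analysis_config()].
#' @return data.frame per window: `chrom`, `window_start`, `window_end`,
#'   `n_probes`, `n_dm_up`, `n_dm_down`, `p_up`, `p_down`, `fdr_up`,
#'   `fdr_down`, `genes` (comma-separated promoters whose TSS falls in the
#'   window).
#' @export
window_scan <- function(probe_results, annotation,
                        config = analysis_config()) {
  stopifnot("probe_call" %in% names(probe_results))
  w <- config$window_size
  idx <- match(probe_results$probe_id, annotation$probes$probe_id)
  chrom <- annotation$probes$chrom[idx]
  mid <- probe_midpoints(annotation)[idx]

  lens <- annotation$chromosome_lengths
  win_list <- lapply(names(lens), function(ch) {
    starts <- seq(0, lens[[ch]] - 1e-9, by = w)
    data.frame(chrom = ch, window_start = starts,
               window_end = pmin(starts + w, lens[[ch]]),
               stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, win_list)
  win_key <- paste0(windows$chrom, ":", windows$window_start)
  probe_key <- paste0(chrom, ":", floor(mid / w) * w)
  wi <- match(probe_key, win_key)

  up <- probe_results$probe_call == "up_in_cpa"
  down <- probe_results$probe_call == "down_in_cpa"
  f <- factor(wi, levels = seq_len(nrow(windows)))
  windows$n_probes <- as.integer(table(f))
  windows$n_dm_up <- as.integer(table(f[up]))
  windows$n_dm_down <- as.integer(table(f[down]))

  n_tot <- nrow(probe_results)
  m_up <- sum(up)
  m_down <- sum(down)
  tail_p <- function(x, m, k) {
    if (m == 0) return(rep(1, length(x)))
    stats::phyper(x - 1, m, n_tot - m, k, lower.tail = FALSE)
  }
  windows$p_up <- tail_p(windows$n_dm_up, m_up, windows$n_probes)
  windows$p_down <- tail_p(windows$n_dm_down, m_down, windows$n_probes)
  windows$fdr_up <- bh_fdr(windows$p_up)
  windows$fdr_down <- bh_fdr(windows$p_down)

  # gene promoters whose TSS falls in each window (Table-3-style reporting)
  pm <- annotation$promoters
  pk <- paste0(pm$chrom, ":", floor(pm$tss / w) * w)
  gi <- match(pk, win_key)
  genes <- vapply(split(pm$gene_symbol, factor(gi, levels = seq_len(nrow(windows)))),
                  paste, character(1), collapse = ",")
  windows$genes <- unname(genes)
  windows
}

#' Significantly enriched windows
#'
#' Filters a [window_scan()] result to windows at or below an FDR threshold
#' in either direction, formatted with 1-based inclusive coordinates.
#'
#' @param windows Output of [window_scan()].
#' @param fdr_threshold Maximum FDR (default 0.2).
#' @return data.frame of enriched windows with `direction` and `fdr`.
#' @export
enriched_windows <- function(windows, fdr_threshold = 0.2) {
  up <- windows[windows$fdr_up <= fdr_threshold & windows$n_dm_up > 0, ]
  down <- windows[windows$fdr_down <= fdr_threshold & windows$n_dm_down > 0, ]
  out <- rbind(
    if (nrow(up)) cbind(up, direction = "up_in_cpa", fdr = up$fdr_up),
    if (nrow(down)) cbind(down, direction = "down_in_cpa", fdr = down$fdr_down)
  )
  if (is.null(out)) return(windows[0, ])
  # human-facing coordinates: 1-based inclusive
  out$location <- sprintf("%s: %d-%d", out$chrom, out$window_start + 1,
                          out$window_end)
  out[order(out$fdr), ]
}

#' Distance-dependent correlation of methylation differences
#'
#' For every intra-chromosomal probe pair separated by at most
#' `max_correlation_distance`, the pair's genomic distance (between interval
#' midpoints) is binned, and the Pearson correlation of the per-probe log2
#' fold differences over the pairs in each bin is reported with a Fisher-z
#' 95% confidence interval. The null envelope is the 2.5-97.5 percentile
#' band of the per-bin correlation under random reassignment of fold
#' differences to probe positions within each chromosome
#' (`config$permutations` rounds). Pair counts per bin are capped by seeded
#' uniform subsampling at `config$pair_cap`.
#'
#' @param probe_results Probe results with `log2fc`.
#' @param annotation A `medip_annotation`.
#' @param config An [analysis_config()].
#' @return data.frame per distance bin: `bin_lower`, `bin_upper`, `n_pairs`,
#'   `pearson_r`, `ci_lower`, `ci_upper`, `null_lower`, `null_upper`. Bins
#'   with fewer than 10 pairs report `NA` correlations.
#' @export
distance_correlation <- function(probe_results, annotation,
                                 config = analysis_config()) {
  set.seed(derive_seed(config$seed, "distance_correlation"))
  idx <- match(probe_results$probe_id, annotation$probes$probe_id)
  chrom <- annotation$probes$chrom[idx]
  pos <- probe_midpoints(annotation)[idx]
  fc <- probe_results$log2fc

  pairs <- build_pairs(chrom, pos, config$max_correlation_distance,
                       config$distance_bin_width, config$pair_cap)
  n_bins <- ceiling(config$max_correlation_distance /
                      config$distance_bin_width)
  bin_lower <- (seq_len(n_bins) - 1) * config$distance_bin_width
  bin_upper <- bin_lower + config$distance_bin_width

  obs <- cor_by_bin(fc, pairs, n_bins)
  n_pairs <- pairs$sizes

  # permutation envelope: shuffle fold differences across positions within
  # each chromosome, keeping the pair/bin structure fixed
  chrom_split <- split(seq_along(fc), chrom)
  perm_r <- matrix(NA_real_, nrow = config$permutations, ncol = n_bins)
  for (b in seq_len(config$permutations)) {
    fc_perm <- fc
    for (ii in chrom_split) fc_perm[ii] <- fc[ii][sample.int(length(ii))]
    perm_r[b, ] <- cor_by_bin(fc_perm, pairs, n_bins)
  }
  env <- apply(perm_r, 2, function(col) {
    if (all(is.na(col))) c(NA_real_, NA_real_)
    else stats::quantile(col, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  })

  ci <- fisher_z_ci(obs, n_pairs)
  data.frame(bin_lower = bin_lower, bin_upper = bin_upper,
             n_pairs = n_pairs, pearson_r = obs,
             ci_lower = ci$lower, ci_upper = ci$upper,
             null_lower = env[1, ], null_upper = env[2, ])
}

# enumerate intra-chromosomal pairs within max_dist, assign distance bins,
# cap per-bin counts by uniform subsampling (uses the current RNG stream).
# Pairs are returned sorted by bin with per-bin sizes so the per-permutation
# correlation reduces to cumulative sums over contiguous segments.
build_pairs <- function(chrom, pos, max_dist, bin_width, pair_cap) {
  n_bins <- ceiling(max_dist / bin_width)
  i_all <- integer(0); j_all <- integer(0)
  for (ii in split(seq_along(pos), chrom)) {
    if (length(ii) < 2) next
    o <- ii[order(pos[ii])]
    p <- pos[o]
    n <- length(p)
    # rightmost partner within max_dist for each probe
    hi <- findInterval(p + max_dist, p)
    reps <- hi - seq_len(n)
    reps[reps < 0] <- 0L
    i_idx <- rep(seq_len(n), reps)
    j_idx <- sequence(reps, from = seq_len(n) + 1L)
    i_all <- c(i_all, o[i_idx])
    j_all <- c(j_all, o[j_idx])
  }
  d <- abs(pos[j_all] - pos[i_all])
  bin <- pmin(floor(d / bin_width) + 1, n_bins)
  # cap per bin
  keep <- unlist(lapply(split(seq_along(bin), bin), function(ix) {
    if (length(ix) > pair_cap) sample(ix, pair_cap) else ix
  }), use.names = FALSE)
  i_all <- i_all[keep]; j_all <- j_all[keep]; bin <- bin[keep]
  o <- order(bin)
  sizes <- tabulate(bin, nbins = n_bins)
  list(i = i_all[o], j = j_all[o], sizes = sizes,
       seg = c(1L, cumsum(sizes) + 1L))  # segment boundaries, length n_bins+1
}

# Pearson r per bin over pairs (x = left probe fc, y = right probe fc);
# pairs are bin-sorted, so per-bin sums are differences of cumulative sums
cor_by_bin <- function(fc, pairs, n_bins) {
  if (length(pairs$i) == 0) return(rep(NA_real_, n_bins))
  x <- fc[pairs$i]; y <- fc[pairs$j]
  seg_sum <- function(v) diff(c(0, cumsum(v))[pairs$seg])
  n <- pairs$sizes
  sx <- seg_sum(x); sy <- seg_sum(y)
  sxx <- seg_sum(x * x); syy <- seg_sum(y * y); sxy <- seg_sum(x * y)
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  r <- (sxy - sx * sy / n) / sqrt(vx * vy)
  r[n < 10 | !is.finite(vx) | !is.finite(vy) | vx <= 0 | vy <= 0] <- NA_real_
  r
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' `atanh(r) +/- z_(1-a/2) / sqrt(n - 3)`, back-transformed.
#'
#' @param r Correlation estimate(s).
#' @param n Number of pairs per estimate.
#' @param conf Confidence level (default 0.95).
#' @return list with vectors `lower`, `upper` (NA where `n < 4` or `r` is NA).
#' @export
fisher_z_ci <- function(r, n, conf = 0.95) {
  z <- atanh(r)
  se <- rep(NA_real_, length(n))
  se[n > 3] <- 1 / sqrt(n[n > 3] - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  list(lower = tanh(z - q * se), upper = tanh(z + q * se))
}
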