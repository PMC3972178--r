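# Normalized CpG density: observed CpG dinucleotide density over the density
# expected from base composition (product of C and G densities). High values
# mark CpG-island-like promoters.

#' Normalized CpG density
#'
#' `(cpg_count / (L - 1)) / ((c_count / L) * (g_count / L))` with `L =
#' length_bp`: the CpG dinucleotide density (over the `L - 1` dinucleotide
#' positions; switch `denominator = "length"` to divide by `L`) relative to
#' the density expected if C and G bases paired at random. Undefined (`NA`)
#' when `c_count` or `g_count` is zero.
#'
#' @param cpg_count,c_count,g_count Non-negative counts (vectorized).
#' @param length_bp Sequence length in bp (>= 2).
#' @param denominator `"positions"` (default, `L - 1`) or `"length"` (`L`).
#' @return Numeric vector of normalized densities (`NA` where undefined).
#' @export
normalized_cpg_density <- function(cpg_count, c_count, g_count, length_bp,
                                   denominator = c("positions", "length")) {
  denominator <- match.arg(denominator)
  if (any(length_bp < 2)) {
    stop("length_bp must be >= 2 (no dinucleotide positions otherwise)",
         call. = FALSE)
  }
  if (any(cpg_count < 0 | c_count < 0 | g_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  dinuc <- if (denominator == "positions") length_bp - 1 else length_bp
  obs <- cpg_count / dinuc
  expd <- (c_count / length_bp) * (g_count / length_bp)
  out <- obs / expd
  out[c_count == 0 | g_count == 0] <- NA_real_
  out
}

#' Base and CpG counts from a DNA sequence
#'
#' Counts C bases, G bases and (non-overlapping, single-strand) CG
#' dinucleotides. `N` bases are excluded from the counts but included in the
#' length; any other character is an error. CG is its own reverse complement,
#' so the strand choice does not change `cpg_count`.
#'
#' @param dna Character scalar over `A`, `C`, `G`, `T`, `N` (case
#'   insensitive).
#' @return list: `cpg_count`, `c_count`, `g_count`, `length`.
#' @export
density_from_sequence <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  s <- toupper(dna)
  if (grepl("[^ACGTN]", s)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
  list(cpg_count = if (hits[1] == -1L) 0L else length(hits),
       c_count = sum(chars == "C"),
       g_count = sum(chars == "G"),
       length = nchar(s))
}

#' Per-promoter CpG density records
#'
#' @param annotation A `medip_annotation` (uses the promoter table's counts).
#' @param denominator Passed to [normalized_cpg_density()].
#' @return data.frame: `promoter_id`, counts, `length_bp`,
#'   `normalized_density`.
#' @export
promoter_cpg_density <- function(annotation,
                                 denominator = c("positions", "length")) {
  pm <- annotation$promoters
  data.frame(
    promoter_id = pm$promoter_id,
    cpg_count = pm$cpg_count, c_count = pm$c_count, g_count = pm$g_count,
    length_bp = pm$length_bp,
    normalized_density = normalized_cpg_density(pm$cpg_count, pm$c_count,
                                                pm$g_count, pm$length_bp,
                                                denominator = denominator),
    stringsAsFactors = FALSE
  )
}

#' Contrast CpG density between promoter call groups
#'
#' Three two-sided rank-sum contrasts of normalized CpG density: promoters
#' called more methylated in CPA vs the rest, less methylated vs the rest,
#' and more- vs less-methylated. Promoters with undefined density are
#' excluded and counted.
#'
#' @param density Output of [promoter_cpg_density()].
#' @param promoter_results Output of [call_promoters()] (needs `dm_call` and
#'   `direction`).
#' @return data.frame: `contrast`, `n_a`, `n_b`, `median_a`, `median_b`,
#'   `p_value`, `n_excluded`.
#' @export
compare_density_groups <- function(density, promoter_results) {
  stopifnot(all(c("dm_call", "direction") %in% names(promoter_results)))
  dens <- stats::setNames(density$normalized_density, density$promoter_id)
  d <- dens[promoter_results$promoter_id]
  defined <- !is.na(d)
  n_excluded <- sum(!defined)
  up <- promoter_results$dm_call &
    promoter_results$direction == "up_in_cpa" & defined
  down <- promoter_results$dm_call &
    promoter_results$direction == "down_in_cpa" & defined
  rest_up <- defined & !up
  rest_down <- defined & !down

  one <- function(name, a, b) {
    if (sum(a) < 2 || sum(b) < 2) {
      stop("contrast '", name, "' needs at least 2 promoters per group",
           call. = FALSE)
    }
    data.frame(contrast = name, n_a = sum(a), n_b = sum(b),
               median_a = stats::median(d[a]), median_b = stats::median(d[b]),
               p_value = rank_sum(d[a], d[b], "two.sided")$p.value,
               n_excluded = n_excluded, stringsAsFactors = FALSE)
  }
  rbind(one("up_vs_rest", up, rest_up),
        one("down_vs_rest", down, rest_down),
        one("up_vs_down", up, down))
}
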