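# Shared fixture builders. Everything is generated in code; sizes are kept
# small enough that the whole suite runs in minutes on one CPU.

# compact synthetic config used by most tests
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_chromosomes = 4, chromosome_length = 2e7,
               n_promoters = 1000, probes_per_promoter = c(3L, 6L),
               planted_fraction = 0.05, effect_log2 = 1.0, effect_sd = 0.2,
               noise_sd = 0.25, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# hand-built annotation: promoters at chosen TSS positions (plus strand),
# one or more probes tiling each region
toy_annotation <- function(tss, chrom = rep("chr1", length(tss)),
                           chrom_len = 1e7, probes_per = 1) {
  n <- length(tss)
  promoters <- data.frame(
    promoter_id = sprintf("P%03d", seq_len(n)),
    gene_symbol = sprintf("G%03d", seq_len(n)),
    chrom = chrom, tss = tss, strand = "+",
    cpg_count = 30L, c_count = 300L, g_count = 300L, length_bp = 1250L,
    stringsAsFactors = FALSE
  )
  k <- rep(probes_per, length.out = n)
  idx <- rep(seq_len(n), k)
  off <- unlist(lapply(k, function(m) round(seq(0, 1190, length.out = m))))
  probes <- data.frame(
    probe_id = sprintf("pr%04d", seq_along(idx)),
    chrom = chrom[idx],
    start = tss[idx] - 1000 + off,
    end = tss[idx] - 1000 + off + 60,
    promoter_id = promoters$promoter_id[idx],
    stringsAsFactors = FALSE
  )
  lens <- tapply(rep(chrom_len, n), chrom, max)
  medip_annotation(setNames(as.numeric(lens), names(lens)), probes, promoters)
}

# probe results table with fabricated statistics, for scan-stage tests
toy_probe_results <- function(annotation, log2fc = NULL, probe_call = NULL,
                              moderated_t = NULL) {
  n <- nrow(annotation$probes)
  data.frame(
    probe_id = annotation$probes$probe_id,
    log2fc = if (is.null(log2fc)) rep(0, n) else log2fc,
    moderated_t = if (is.null(moderated_t)) rep(0, n) else moderated_t,
    p_value = rep(1, n),
    probe_call = if (is.null(probe_call)) rep("none", n) else probe_call,
    stringsAsFactors = FALSE
  )
}

# genome tiled by 1 Mb blocks of 3 probes sharing a block-level methylation
# difference (within-block correlation ~0.35) plus probe-level noise: a
# spatially correlated signal whose correlation vanishes beyond 1 Mb. Many
# chromosomes keep the long-range correlation estimator well behaved.
make_block_fixture <- function(seed, n_chrom = 30, sd_block = 0.22,
                               sd_noise = 0.3) {
  set.seed(seed)
  clen <- 2e7; n_block <- 20
  pos_all <- c(); chrom_all <- c(); fc_all <- c()
  for (ch in seq_len(n_chrom)) {
    bpos <- sort(as.integer(outer(c(1e5, 5.5e5, 9e5),
                                  (seq_len(n_block) - 1) * 1e6, "+")))
    b_fc <- rep(rnorm(n_block, 0, sd_block), each = 3)
    fc <- b_fc + rnorm(length(bpos), 0, sd_noise)
    pos_all <- c(pos_all, bpos)
    fc_all <- c(fc_all, fc)
    chrom_all <- c(chrom_all, rep(paste0("chr", ch), length(bpos)))
  }
  ann <- toy_annotation(tss = pos_all, chrom = chrom_all, chrom_len = clen)
  list(annotation = ann,
       probe_results = toy_probe_results(ann, log2fc = fc_all))
}

# exact rank-sum p-value by enumeration of all group assignments
enum_ranksum_p <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y)
  v <- c(x, y)
  r <- rank(v)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  U_all <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_greater <- mean(U_all >= U_obs)
  p_less <- mean(U_all <= U_obs)
  switch(alternative,
         greater = p_greater,
         less = p_less,
         two.sided = min(2 * min(p_greater, p_less), 1))
}

# hand-executed BH step-up
stepup_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
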