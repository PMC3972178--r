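# Chromosome overrepresentation, window enrichment scan, and
# distance-dependent correlation of methylation differences.

test_that("chromosome enrichment equals the hypergeometric tail computed by enumeration", {
  # 100 promoters: 10 on chr1, 90 on chr2; all 10 dm calls on chr1
  ann <- toy_annotation(tss = seq(2000, by = 5000, length.out = 100),
                        chrom = rep(c("chr1", "chr2"), c(10, 90)))
  prom <- data.frame(promoter_id = ann$promoters$promoter_id,
                     direction = "up_in_cpa",
                     dm_call = rep(c(TRUE, FALSE), c(10, 90)))
  enr <- chromosome_enrichment(prom, ann)
  # P(X >= 10) = P(X = 10) = choose(10,10) * choose(90,0) / choose(100,10)
  p_hand <- choose(10, 10) * choose(90, 0) / choose(100, 10)
  expect_equal(enr$p[enr$chrom == "chr1"], p_hand, tolerance = 1e-12)
  expect_equal(enr$fdr, stepup_bh(enr$p), tolerance = 1e-12)

  none <- prom; none$dm_call <- FALSE
  expect_error(chromosome_enrichment(none, ann), "no differentially")
})

test_that("proportionally spread calls are not enriched anywhere", {
  # calls spread proportionally to promoter counts: no chromosome stands out
  set.seed(10)
  min_p <- vapply(1:40, function(s) {
    set.seed(s)
    ann <- toy_annotation(tss = rep(seq(2000, by = 5000, length.out = 50), 4),
                          chrom = rep(paste0("chr", 1:4), each = 50))
    dm <- sample(c(TRUE, FALSE), 200, replace = TRUE, prob = c(0.1, 0.9))
    prom <- data.frame(promoter_id = ann$promoters$promoter_id,
                       direction = "up_in_cpa", dm_call = dm)
    if (!any(dm)) return(1)
    min(chromosome_enrichment(prom, ann)$p)
  }, numeric(1))
  # smallest of 4 one-sided p-values; should rarely dip very low
  expect_gte(mean(min_p >= 0.05), 0.7)
  expect_gte(min(min_p), 0.005)
})

test_that("window scan equals the hypergeometric tail and conserves counts", {
  # 100 single-probe promoters in 10 windows of 500 kb on one 5 Mb chromosome
  tss <- as.integer(seq(25000, 5e6 - 25000, length.out = 100))
  ann <- toy_annotation(tss = tss, chrom_len = 5e6)
  mid <- (ann$probes$start + ann$probes$end) / 2
  hot <- floor(mid / 5e5) == 2  # probes in the third window
  k_hot <- sum(hot)
  call <- rep("none", 100)
  call[which(hot)[1:8]] <- "down_in_cpa"
  pr <- toy_probe_results(ann, probe_call = call)
  win <- window_scan(pr, ann, analysis_config())

  expect_equal(sum(win$n_probes), 100)
  expect_equal(sum(win$n_dm_down), 8)
  # enumeration oracle: P(X >= 8) over the hypergeometric support
  xs <- 8:min(k_hot, 8)
  p_hand <- sum(choose(8, xs) * choose(92, k_hot - xs)) / choose(100, k_hot)
  hot_row <- win$n_dm_down == 8
  expect_equal(win$p_down[hot_row], p_hand, tolerance = 1e-12)
  expect_true(all(win$p_down[!hot_row] == 1))

  ew <- enriched_windows(win, 0.2)
  expect_identical(ew$direction, "down_in_cpa")
  expect_identical(nrow(ew), 1L)

  # zero dm probes: all p = 1, nothing enriched
  pr0 <- toy_probe_results(ann)
  win0 <- window_scan(pr0, ann, analysis_config())
  expect_true(all(win0$p_up == 1) && all(win0$p_down == 1))
  expect_identical(nrow(enriched_windows(win0, 0.2)), 0L)
})

test_that("shuffling probe positions destroys window enrichment", {
  sc <- small_sim_config(cluster_block_length = 5e5, planted_fraction = 0.05,
                         seed = 21)
  ann <- generate_annotation(sc)
  sim <- generate_matrix(sc, ann)
  pr <- probe_stats(sim$matrix)
  win <- window_scan(pr, ann, analysis_config())
  expect_gte(nrow(enriched_windows(win, 0.2)), 1)

  # permute call labels across probes: enrichment vanishes and window
  # p-values for windows holding calls spread out
  set.seed(99)
  pr_shuf <- pr
  pr_shuf$probe_call <- sample(pr$probe_call)
  pr_shuf$log2fc <- sample(pr$log2fc)
  win_shuf <- window_scan(pr_shuf, ann, analysis_config())
  expect_lt(nrow(enriched_windows(win_shuf, 0.2)),
            nrow(enriched_windows(win, 0.2)))
  ks <- suppressWarnings(ks.test(win_shuf$p_down[win_shuf$n_dm_down > 0],
                                 "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clustered planted signal is recovered by the window scan across seeds", {
  hits <- vapply(1:10, function(s) {
    sc <- small_sim_config(cluster_block_length = 5e5, planted_fraction = 0.05,
                           seed = s)
    ann <- generate_annotation(sc)
    sim <- generate_matrix(sc, ann)
    pr <- probe_stats(sim$matrix)
    nrow(enriched_windows(window_scan(pr, ann, analysis_config()), 0.2)) >= 1
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("distance correlation: degenerate, null-calibrated, and planted-structure cases", {
  cfg <- analysis_config(max_correlation_distance = 6e6,
                         distance_bin_width = 5e5, permutations = 100,
                         seed = 3)

  # constant fold differences: correlation undefined
  ann_c <- toy_annotation(tss = seq(2000, by = 3000, length.out = 60))
  pr_c <- toy_probe_results(ann_c, log2fc = rep(0.5, 60))
  dc_c <- distance_correlation(pr_c, ann_c, cfg)
  expect_true(all(is.na(dc_c$pearson_r[dc_c$n_pairs >= 10])))

  # i.i.d. fold differences: the permutation envelope is exchangeable with
  # the observed correlation, so the per-bin exceedance rate is the nominal
  # 5%. Pool bins over 5 seeds and allow the binomial 99% margin
  # (qbinom(0.99, 60, 0.05) = 7 exceedances).
  n_out <- 0; n_bins <- 0
  for (s in 1:5) {
    set.seed(30 + s)
    ann_n <- toy_annotation(tss = as.integer(seq(2000, 2e7 - 2000,
                                                 length.out = 600)),
                            chrom_len = 2e7)
    pr_n <- toy_probe_results(ann_n, log2fc = rnorm(600, 0, 0.3))
    cfg_s <- analysis_config(max_correlation_distance = 6e6,
                             distance_bin_width = 5e5, permutations = 100,
                             seed = 30 + s)
    dc_n <- distance_correlation(pr_n, ann_n, cfg_s)
    ok <- dc_n$n_pairs >= 10
    inside <- dc_n$pearson_r >= dc_n$null_lower &
      dc_n$pearson_r <= dc_n$null_upper
    n_out <- n_out + sum(!inside[ok]); n_bins <- n_bins + sum(ok)
  }
  expect_lte(n_out, qbinom(0.99, n_bins, 0.05))

  # planted 1 Mb correlated blocks: r above the envelope below 1 Mb; beyond
  # the block scale the correlation vanishes, though block-level value reuse
  # inflates the long-range sampling variance of r slightly above the
  # iid envelope, so a small exceedance allowance is kept
  fx <- make_block_fixture(seed = 32)
  dc_b <- distance_correlation(fx$probe_results, fx$annotation, cfg)
  short <- dc_b$bin_upper <= 1e6
  long <- dc_b$bin_lower >= 4e6
  expect_true(all(dc_b$pearson_r[short] > dc_b$null_upper[short]))
  inside_long <- dc_b$pearson_r[long] >= dc_b$null_lower[long] &
    dc_b$pearson_r[long] <= dc_b$null_upper[long]
  expect_gte(mean(inside_long), 0.75)
})

test_that("Fisher-z confidence intervals have near-nominal coverage", {
  set.seed(77)
  rho <- 0.3; n <- 50
  covered <- vapply(seq_len(1000), function(i) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- cor(x, y)
    ci <- fisher_z_ci(r, n)
    ci$lower <= rho && rho <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
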