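# Rank-sum primitive, promoter enrichment aggregation, BH FDR and the joint
# differential-methylation call.

test_that("rank_sum matches exact enumeration and handles ties/degeneracy", {
  expect_equal(rank_sum(c(2, 3), c(-1, 0, 1), "greater")$p.value, 0.1)
  expect_equal(rank_sum(c(1, 2, 3), c(1, 2, 3), "two.sided")$p.value, 1)
  expect_error(rank_sum(numeric(0), 1:3), "non-empty")

  # exact path agrees with enumeration over random tie-free cases
  set.seed(1)
  for (rep in 1:25) {
    n1 <- sample(1:5, 1); n2 <- sample(1:6, 1)
    x <- sample(seq_len(50), n1); y <- sample(setdiff(seq_len(50), x), n2)
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(rank_sum(x, y, alt)$p.value, enum_ranksum_p(x, y, alt),
                   tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d %s", n1, n2, alt))
    }
  }

  # approximation is close to enumeration at moderate n (forced approx)
  set.seed(2)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    p_apx <- rank_sum(x, y, "greater", exact = FALSE)$p.value
    p_enu <- enum_ranksum_p(x, y, "greater")
    expect_lt(abs(p_apx - p_enu), 0.01)
  }

  # agreement with wilcox.test (independent implementation) incl. ties
  set.seed(3)
  x <- rnorm(30); y <- rnorm(25)
  expect_equal(rank_sum(x, y, "two.sided")$p.value,
               wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-10)
  xt <- round(rnorm(20), 1); yt <- round(rnorm(20), 1)  # ties
  expect_equal(rank_sum(xt, yt, "greater")$p.value,
               wilcox.test(xt, yt, alternative = "greater", correct = TRUE,
                           exact = FALSE)$p.value, tolerance = 1e-10)
  # small tie-free case: exact paths of both implementations agree
  expect_equal(rank_sum(1:4, c(0.5, 2.5, 6, 7, 8), "less")$p.value,
               wilcox.test(1:4, c(0.5, 2.5, 6, 7, 8),
                           alternative = "less")$p.value, tolerance = 1e-12)
})

test_that("promoter enrichment equals per-promoter rank-sum against the rest of the array", {
  ann <- toy_annotation(tss = seq(2000, by = 5000, length.out = 5),
                        probes_per = c(4, 3, 5, 4, 4))
  set.seed(8)
  n <- nrow(ann$probes)
  pr <- toy_probe_results(ann, moderated_t = rnorm(n))
  enr <- promoter_enrichment(pr, ann)
  prom_of <- ann$probes$promoter_id
  for (i in seq_len(nrow(enr))) {
    own <- pr$moderated_t[prom_of == enr$promoter_id[i]]
    rest <- pr$moderated_t[prom_of != enr$promoter_id[i]]
    expect_equal(enr$p_up[i], rank_sum(own, rest, "greater")$p.value,
                 tolerance = 1e-12)
    expect_equal(enr$p_down[i], rank_sum(own, rest, "less")$p.value,
                 tolerance = 1e-12)
  }
  expect_equal(enr$promoter_p, pmin(enr$p_up, enr$p_down))

  # promoter holding the k largest t on a small array: p_up = 1 / choose(N, k)
  ann2 <- toy_annotation(tss = seq(2000, by = 5000, length.out = 5),
                         probes_per = 4)  # N = 20 <= 25, exact path
  tvals <- seq_len(20) / 100
  tvals[1:4] <- 10 + 1:4  # promoter P001 probes are the 4 largest
  pr2 <- toy_probe_results(ann2, moderated_t = tvals)
  enr2 <- promoter_enrichment(pr2, ann2)
  expect_equal(enr2$p_up[enr2$promoter_id == "P001"], 1 / choose(20, 4),
               tolerance = 1e-12)

  # single-promoter array: degenerate background
  ann3 <- toy_annotation(tss = 2000, probes_per = 6)
  pr3 <- toy_probe_results(ann3, moderated_t = rnorm(6))
  expect_error(promoter_enrichment(pr3, ann3), "degenerate background")
})

test_that("bh_fdr equals the hand-executed step-up and validates input", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- runif(200)^2
  expect_equal(bh_fdr(p), stepup_bh(p), tolerance = 1e-12)
  # monotone non-decreasing in p
  o <- order(p)
  expect_true(all(diff(bh_fdr(p)[o]) >= -1e-15))
})

test_that("dm calls require both the FDR cut and a direction-matching called probe", {
  ann <- toy_annotation(tss = seq(2000, by = 5000, length.out = 40),
                        probes_per = 3)
  set.seed(5)
  n <- nrow(ann$probes)
  tvals <- rnorm(n)
  tvals[1:3] <- c(8, 9, 10)    # P001 strongly up
  tvals[4:6] <- c(-8, -9, -10) # P002 strongly down
  fc <- tvals / 10
  calls <- ifelse(abs(tvals) > 5 & abs(fc) >= 0.25,
                  ifelse(fc > 0, "up_in_cpa", "down_in_cpa"), "none")
  pr <- toy_probe_results(ann, log2fc = fc, probe_call = calls,
                          moderated_t = tvals)
  prom <- call_promoters(promoter_enrichment(pr, ann), pr, ann,
                         analysis_config())
  expect_true(prom$dm_call[prom$promoter_id == "P001"])
  expect_true(prom$dm_call[prom$promoter_id == "P002"])
  expect_identical(prom$direction[prom$promoter_id == "P001"], "up_in_cpa")
  expect_identical(prom$direction[prom$promoter_id == "P002"], "down_in_cpa")

  # kill the probe calls: same FDR, no matching probe, no dm call
  pr_none <- pr; pr_none$probe_call <- "none"
  prom2 <- call_promoters(promoter_enrichment(pr_none, ann), pr_none, ann,
                          analysis_config())
  expect_false(any(prom2$dm_call))

  # count conservation: calls partition into up + down
  expect_identical(sum(prom$dm_call),
                   sum(prom$dm_call & prom$direction == "up_in_cpa") +
                     sum(prom$dm_call & prom$direction == "down_in_cpa"))
})

test_that("planted promoters are recovered with controlled FDP and direction", {
  scores <- lapply(1:3, function(s) {
    sc <- small_sim_config(seed = s)
    ann <- generate_annotation(sc)
    sim <- generate_matrix(sc, ann)
    prom <- promoter_stats(probe_stats(sim$matrix), ann)
    score_recovery(prom, sim$truth)
  })
  for (sc in scores) {
    expect_gte(sc$sensitivity, 0.9)
    expect_lte(sc$fdp, 0.25)
    expect_gte(sc$direction_accuracy, 0.99)
  }
})

test_that("false calls among calls stay near the FDR target on null data", {
  fdp <- vapply(1:20, function(s) {
    sc <- small_sim_config(planted_fraction = 0, n_promoters = 1000, seed = s)
    ann <- generate_annotation(sc)
    sim <- generate_matrix(sc, ann)
    prom <- promoter_stats(probe_stats(sim$matrix), ann)
    if (sum(prom$dm_call) == 0) 0 else 1  # every call on null data is false
  }, numeric(1))
  # with no signal, calls should be rare enough that mean false-call fraction
  # stays at or below threshold + slack
  expect_lte(mean(fdp), 0.25)
})
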