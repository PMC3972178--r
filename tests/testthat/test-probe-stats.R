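# Probe-level fits, the empirical-Bayes prior, and moderated t-statistics.

make_matrix <- function(values, groups) {
  medip_matrix(values, sprintf("p%d", seq_len(nrow(values))),
               sprintf("s%d", seq_len(ncol(values))), groups)
}

test_that("fit_probe_models matches a direct two-pass mean/variance computation", {
  # degenerate cases first
  m <- make_matrix(rbind(c(1, 1, 0, 0, 0), c(2, 2, 2, 2, 2)),
                   c("CPA", "CPA", "control", "control", "control"))
  fits <- fit_probe_models(m)
  expect_equal(fits$log2fc, c(1, 0))
  expect_equal(fits$s2, c(0, 0))
  expect_equal(fits$df, c(3L, 3L))

  set.seed(42)
  v <- matrix(rnorm(50 * 20), 50, 20)
  groups <- c(rep("CPA", 8), rep("control", 12))
  fits <- fit_probe_models(make_matrix(v, groups))
  for (i in c(1, 17, 50)) {
    a <- v[i, 1:8]; b <- v[i, 9:20]
    expect_equal(fits$log2fc[i], mean(a) - mean(b), tolerance = 1e-12)
    sp2 <- ((8 - 1) * var(a) + (12 - 1) * var(b)) / 18
    expect_equal(fits$s2[i], sp2, tolerance = 1e-12)
  }
  expect_error(fit_probe_models(make_matrix(v[, c(1, 9:20)],
                                            groups[c(1, 9:20)])),
               "at least 2")
})

test_that("prior estimation recovers simulated hyperparameters and handles edge cases", {
  # equal variances: no excess dispersion, d0 = Inf, s0^2 = common value
  pr <- estimate_prior(rep(0.04, 100), 18)
  expect_identical(pr$prior_df, Inf)
  expect_equal(pr$prior_var, 0.04, tolerance = 1e-9)

  expect_error(estimate_prior(rep(0, 100), 18), "zero")
  expect_error(estimate_prior(runif(5), 18), "at least 10")

  # hierarchical simulation: s^2 / s0^2 ~ F(d, d0) marginally
  set.seed(101)
  d <- 18; d0 <- 4; s0sq <- 0.04
  s2 <- s0sq * rf(10000, d, d0)
  pr <- estimate_prior(s2, d)
  expect_lt(abs(pr$prior_df - d0) / d0, 0.15)
  expect_lt(abs(pr$prior_var - s0sq) / s0sq, 0.15)
})

test_that("moderated t has the documented limits and matches limma", {
  set.seed(7)
  # heterogeneous true variances so the prior df is finite
  v <- matrix(rnorm(200 * 20, sd = rep(sqrt(0.04 * rf(200, 18, 6)), 20)),
              200, 20)
  v[1, ] <- 0.5  # constant probe: log2fc 0
  groups <- c(rep("CPA", 8), rep("control", 12))
  m <- make_matrix(v, groups)
  fits <- fit_probe_models(m)

  # d0 -> 0 limit: ordinary pooled two-sample t
  res0 <- moderated_t(fits, ebayes_prior(0, 1))
  plain_t <- fits$log2fc / sqrt(fits$s2 * (1 / 8 + 1 / 12))
  plain_p <- 2 * pt(-abs(plain_t), 18)
  expect_equal(res0$moderated_t[-1], plain_t[-1], tolerance = 1e-9)
  expect_equal(res0$p_value[-1], plain_p[-1], tolerance = 1e-9)
  # and against t.test as an independent implementation
  tt <- t.test(v[5, 1:8], v[5, 9:20], var.equal = TRUE)
  expect_equal(res0$moderated_t[5], unname(tt$statistic), tolerance = 1e-9)
  expect_equal(res0$p_value[5], tt$p.value, tolerance = 1e-9)

  # d0 = Inf: statistic is log2fc over the common-variance standard error
  resI <- moderated_t(fits, ebayes_prior(Inf, 0.09))
  expect_equal(resI$moderated_t,
               fits$log2fc / sqrt(0.09 * (1 / 8 + 1 / 12)),
               tolerance = 1e-12)

  # zero fold difference: t = 0, p = 1
  res <- moderated_t(fits)
  expect_equal(res$moderated_t[1], 0)
  expect_equal(res$p_value[1], 1)

  # shrinkage: posterior variance between s^2 and s0^2
  pr <- attr(res, "prior")
  lo <- pmin(fits$s2, pr$prior_var); hi <- pmax(fits$s2, pr$prior_var)
  expect_true(all(res$posterior_var >= lo - 1e-12 &
                    res$posterior_var <= hi + 1e-12))

  # monotonicity in |log2fc| at fixed variance
  f2 <- fits; f2$log2fc <- seq(0.1, 2, length.out = nrow(f2))
  f2$s2 <- 0.05
  r2 <- moderated_t(f2, ebayes_prior(4, 0.05))
  expect_true(all(diff(abs(r2$moderated_t)) > 0))

  # full agreement with limma on the zero-variance-free probes (this package
  # excludes exactly-zero variances from prior fitting; limma winsorises
  # them, so the comparison set holds none)
  design <- cbind(Intercept = 1, CPA = as.numeric(groups == "CPA"))
  fit <- limma::eBayes(limma::lmFit(v[-1, ], design))
  m2 <- make_matrix(v[-1, ], groups)
  res2 <- moderated_t(fit_probe_models(m2))
  pr2 <- attr(res2, "prior")
  expect_equal(pr2$prior_df, fit$df.prior, tolerance = 1e-6)
  expect_equal(pr2$prior_var, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res2$moderated_t, fit$t[, "CPA"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(res2$p_value, fit$p.value[, "CPA"], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("probe calls enforce both thresholds with direction from the fold sign", {
  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    log2fc = c(0.3, 0.1, 0.5, -0.3),
                    p_value = c(0.04, 0.04, 0.06, 0.04))
  called <- call_probes(res, analysis_config())
  expect_identical(called$probe_call, c("up_in_cpa", "none", "none",
                                        "down_in_cpa"))
})

test_that("probe-level type-I error is nominal on null data", {
  # planted_fraction 0, 500 promoters x 4 probes = 2000 probes, 5 seeds
  fractions <- vapply(1:5, function(s) {
    sc <- small_sim_config(planted_fraction = 0, n_promoters = 500,
                           probes_per_promoter = c(4L, 4L), seed = s)
    ann <- generate_annotation(sc)
    mat <- generate_matrix(sc, ann)$matrix
    res <- probe_stats(mat)
    mean(res$p_value <= 0.05)
  }, numeric(1))
  expect_true(all(fractions >= 0.03 & fractions <= 0.07))
})
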