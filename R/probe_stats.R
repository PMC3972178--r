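# Probe-level statistics: two-group pooled-variance fits and empirical-Bayes
# moderated t-statistics. The linear model assumes a common within-group
# variance per probe (Student, not Welch), and per-probe variances are shrunk
# toward a prior estimated across all probes by matching moments of
# log sample variances (digamma/trigamma equations).

#' Fit per-probe two-group models
#'
#' For every probe: the log2 fold difference (mean CPA minus mean control),
#' the pooled within-group variance, and its residual degrees of freedom
#' `n1 + n2 - 2`.
#'
#' @param mat A `medip_matrix`.
#' @return data.frame with columns `probe_id`, `log2fc`, `s2` (pooled
#'   residual variance), `df`, plus attributes `n_cpa`/`n_control`.
#' @export
fit_probe_models <- function(mat) {
  stopifnot(inherits(mat, "medip_matrix"))
  gi <- group_indices(mat)
  n1 <- length(gi$cpa)
  n2 <- length(gi$control)
  if (n1 < 2 || n2 < 2) {
    stop("pooled variance undefined: each group needs n >= 2", call. = FALSE)
  }
  v <- mat$values
  m1 <- rowMeans(v[, gi$cpa, drop = FALSE])
  m2 <- rowMeans(v[, gi$control, drop = FALSE])
  ss1 <- rowSums((v[, gi$cpa, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, gi$control, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  out <- data.frame(probe_id = mat$probe_ids,
                    log2fc = m1 - m2,
                    s2 = (ss1 + ss2) / df,
                    df = df,
                    stringsAsFactors = FALSE)
  attr(out, "n_cpa") <- n1
  attr(out, "n_control") <- n2
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments on log sample variances: with per-probe variances
#' s^2 ~ s0^2 * chi^2_d / d scaled by an inverse-chi-square prior with d0
#' degrees of freedom, e = log(s^2) - digamma(d/2) + log(d/2) has mean
#' log(s0^2) + log(d0/2) - digamma(d0/2) and excess variance trigamma(d0/2)
#' over trigamma(d/2). d0 solves the trigamma equation by Newton iteration
#' (tolerance 1e-8) with a bisection fallback; when the empirical variance of
#' log s^2 does not exceed its theoretical minimum, d0 = Inf (all variances
#' consistent with a single common value).
#'
#' Variances exactly zero are floored at 1e-12 and excluded from prior
#' fitting so degenerate probes cannot poison the prior.
#'
#' @param s2 Numeric vector of per-probe pooled variances.
#' @param df Residual degrees of freedom (scalar; the two-group design gives
#'   every probe the same df).
#' @return A list of class `ebayes_prior`: `prior_df` (d0, possibly `Inf`),
#'   `prior_var` (s0^2), `n_used`.
#' @export
estimate_prior <- function(s2, df) {
  df <- unique(df)
  if (length(df) != 1L) stop("expected a single residual df", call. = FALSE)
  ok <- is.finite(s2) & s2 > 1e-12
  if (all(!ok) || all(s2 <= 1e-12)) {
    stop("all residual variances are zero; prior undefined", call. = FALSE)
  }
  s2_fit <- s2[ok]
  if (length(s2_fit) < 10) {
    stop("need at least 10 probes with positive variance to estimate the prior (got ",
         length(s2_fit), ")", call. = FALSE)
  }

  if (diff(range(s2_fit)) <= 1e-15 * max(s2_fit)) {
    # zero dispersion: every probe already sits at the common variance
    return(structure(list(prior_df = Inf, prior_var = s2_fit[1],
                          n_used = length(s2_fit)), class = "ebayes_prior"))
  }

  z <- log(s2_fit)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2) * n / (n - 1) - trigamma(df / 2)

  if (excess <= 0) {
    return(structure(list(prior_df = Inf, prior_var = exp(ebar),
                          n_used = n), class = "ebayes_prior"))
  }
  half_d0 <- trigamma_inverse(excess)
  d0 <- 2 * half_d0
  s0sq <- exp(ebar + digamma(half_d0) - log(half_d0))
  structure(list(prior_df = d0, prior_var = s0sq, n_used = n),
            class = "ebayes_prior")
}

#' Construct an empirical-Bayes prior directly
#'
#' Mostly useful for studying limiting behaviour: `prior_df = 0` recovers the
#' ordinary pooled t-test, `prior_df = Inf` a z-test against the common
#' variance.
#'
#' @param prior_df Prior degrees of freedom d0 (>= 0, may be `Inf`).
#' @param prior_var Prior variance s0^2 (> 0).
#' @return An `ebayes_prior`.
#' @export
ebayes_prior <- function(prior_df, prior_var) {
  if (prior_df < 0) stop("'prior_df' must be >= 0", call. = FALSE)
  if (prior_var <= 0) stop("'prior_var' must be > 0", call. = FALSE)
  structure(list(prior_df = prior_df, prior_var = prior_var, n_used = NA),
            class = "ebayes_prior")
}

# solve trigamma(y) = x for y > 0: Newton in log space with bisection
# fallback; trigamma is strictly decreasing so the root is unique
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 100) {
  if (x <= 0) return(Inf)
  # large x -> small y: trigamma(y) ~ 1/y^2; small x -> y ~ 1/x
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y_new <- y + dif
    if (!is.finite(y_new) || y_new <= 0) break
    if (abs(dif) < tol * y) return(y_new)
    y <- y_new
  }
  # bisection fallback on a bracketing interval
  lo <- 1e-8; hi <- 1e8
  if (trigamma(lo) < x || trigamma(hi) > x) return(y)
  for (i in seq_len(200)) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > x) lo <- mid else hi <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

#' Moderated t-statistics and p-values
#'
#' Posterior variance per probe is the df-weighted blend of the probe's
#' pooled variance and the prior, `(d0*s0^2 + df*s^2) / (d0 + df)`; the
#' moderated t is the group difference over its posterior standard error and
#' is referred to a t distribution with `d0 + df` degrees of freedom
#' (standard normal when `d0` is infinite).
#'
#' @param fits Output of [fit_probe_models()].
#' @param prior An `ebayes_prior`, or `NULL` to estimate it from `fits`.
#' @return `fits` with added columns `posterior_var`, `moderated_t`,
#'   `p_value`; attribute `prior` carries the prior used.
#' @export
moderated_t <- function(fits, prior = NULL) {
  n1 <- attr(fits, "n_cpa")
  n2 <- attr(fits, "n_control")
  if (is.null(n1) || is.null(n2)) {
    stop("'fits' must come from fit_probe_models()", call. = FALSE)
  }
  if (is.null(prior)) prior <- estimate_prior(fits$s2, fits$df)
  stopifnot(inherits(prior, "ebayes_prior"))
  d0 <- prior$prior_df
  s0sq <- prior$prior_var
  df <- fits$df

  post_var <- if (is.infinite(d0)) {
    rep(s0sq, nrow(fits))
  } else {
    (d0 * s0sq + df * fits$s2) / (d0 + df)
  }
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  tstat <- fits$log2fc / se
  p <- if (is.infinite(d0)) {
    2 * stats::pnorm(-abs(tstat))
  } else {
    2 * stats::pt(-abs(tstat), df = d0 + df)
  }
  out <- fits
  out$posterior_var <- post_var
  out$moderated_t <- tstat
  out$p_value <- p
  attr(out, "prior") <- prior
  attr(out, "n_cpa") <- n1
  attr(out, "n_control") <- n2
  out
}

#' Flag probes passing the probe-level call criteria
#'
#' A probe is called differentially methylated when its moderated-t p-value
#' is at most `probe_p_threshold` (uncorrected) and its absolute log2 fold
#' difference is at least `min_abs_log2fc`; the call direction follows the
#' sign of the fold difference.
#'
#' @param probe_results Output of [moderated_t()].
#' @param config An [analysis_config()].
#' @return `probe_results` with added `probe_call` column
#'   (`up_in_cpa` / `down_in_cpa` / `none`).
#' @export
call_probes <- function(probe_results, config = analysis_config()) {
  stopifnot(all(c("p_value", "log2fc") %in% names(probe_results)))
  pass <- probe_results$p_value <= config$probe_p_threshold &
    abs(probe_results$log2fc) >= config$min_abs_log2fc
  call <- rep("none", nrow(probe_results))
  call[pass & probe_results$log2fc > 0] <- "up_in_cpa"
  call[pass & probe_results$log2fc < 0] <- "down_in_cpa"
  probe_results$probe_call <- call
  probe_results
}

#' Probe-level pipeline stage
#'
#' Convenience wrapper: fit, estimate prior, moderate, call.
#'
#' @param mat A `medip_matrix`.
#' @param config An [analysis_config()].
#' @return data.frame of per-probe results with calls.
#' @export
probe_stats <- function(mat, config = analysis_config()) {
  fits <- fit_probe_models(mat)
  res <- moderated_t(fits, estimate_prior(fits$s2, fits$df))
  call_probes(res, config)
}
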