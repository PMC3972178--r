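# Cohort group-comparison statistics from printed summaries: pooled
# two-sample t-tests from (mean, sd, n) and two-tailed Fisher exact tests
# from 2x2 counts. A transcription of the study's case/control
# characteristics table ships as a package fixture.

#' Pooled two-sample t-test from summary statistics
#'
#' Student's t with pooled variance (the convention implied by the study's
#' printed degrees of freedom): `t = (mean_a - mean_b) / sqrt(sp2 * (1/n_a +
#' 1/n_b))` with `sp2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a+n_b-2)`.
#'
#' @param mean_a,sd_a,n_a Group A summary (here: control).
#' @param mean_b,sd_b,n_b Group B summary (here: CPA).
#' @return list: `t`, `df`, `p` (two-sided).
#' @export
pooled_t_from_summaries <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd_a < 0 || sd_b < 0) stop("sds must be >= 0", call. = FALSE)
  if (sd_a == 0 && sd_b == 0) {
    stop("pooled variance undefined: both sds are zero", call. = FALSE)
  }
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Table layout `[[a, b], [c, d]]` (rows = groups, columns = yes/no). The
#' two-tailed p-value is the point-probability method: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability is at most the observed one (relative tolerance 1 +
#' 1e-7). The odds ratio is the sample `ad / bc` (`Inf` when `bc = 0`).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return list: `odds_ratio`, `p` (two-tailed), `support` (data.frame of the
#'   full hypergeometric support: `x`, `prob`).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  m <- a + b     # row 1 total (group A)
  n <- c + d     # row 2 total
  k <- a + c     # column 1 total (yes)
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p = min(p, 1),
       support = data.frame(x = xs, prob = probs))
}

empty_cohort_table <- function() {
  data.frame(variable = character(), type = character(),
             mean_control = numeric(), sd_control = numeric(),
             n_control = integer(), mean_cpa = numeric(), sd_cpa = numeric(),
             n_cpa = integer(), control_yes = integer(),
             control_no = integer(), cpa_yes = integer(), cpa_no = integer(),
             stringsAsFactors = FALSE)
}

#' Read a cohort summary table
#'
#' TSV with one row per variable; `type` is `summary` (uses `mean_*`, `sd_*`,
#' `n_*`) or `count` (uses `*_yes`, `*_no`). The packaged transcription of
#' the study's case/control characteristics table is at
#' `system.file("extdata", "cohort_table1.tsv", package = "medipscan")`.
#'
#' @param path TSV path.
#' @return data.frame of class `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- names(empty_cohort_table())
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$type %in% c("summary", "count"))) {
    stop("cohort variable 'type' must be 'summary' or 'count'", call. = FALSE)
  }
  tab <- tab[, need]
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Group-comparison report for a cohort table
#'
#' Applies the pooled t-test to `summary` variables and the two-tailed Fisher
#' exact test to `count` variables. Group A is control, group B is CPA, so t
#' is signed control minus CPA. Per-variable errors are caught and flagged
#' without aborting the remaining rows. Statistics are reported at full
#' precision together with conventionally rounded display values (t to 2
#' decimals, Fisher p to 3).
#'
#' @param cohort A `cohort_table` (see [read_cohort_table()]).
#' @return data.frame: `variable`, `test`, `statistic`, `df`, `p_value`,
#'   `statistic_2dp`, `p_3dp`, `odds_ratio`, `error`.
#' @export
cohort_report <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0) {
    return(data.frame(variable = character(), test = character(),
                      statistic = numeric(), df = numeric(),
                      p_value = numeric(), statistic_2dp = numeric(),
                      p_3dp = numeric(), odds_ratio = numeric(),
                      error = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    v <- cohort[i, ]
    out <- data.frame(variable = v$variable, test = NA_character_,
                      statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, statistic_2dp = NA_real_,
                      p_3dp = NA_real_, odds_ratio = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      if (v$type == "summary") {
        r <- pooled_t_from_summaries(v$mean_control, v$sd_control,
                                     v$n_control, v$mean_cpa, v$sd_cpa,
                                     v$n_cpa)
        out$test <- "pooled_t"
        out$statistic <- r$t
        out$df <- r$df
        out$p_value <- r$p
        out$statistic_2dp <- round(r$t, 2)
      } else {
        r <- fisher_exact_2x2(v$control_yes, v$control_no, v$cpa_yes,
                              v$cpa_no)
        out$test <- "fisher_exact"
        out$p_value <- r$p
        out$odds_ratio <- r$odds_ratio
      }
      out$p_3dp <- round(out$p_value, 3)
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
    res
  })
  do.call(rbind, rows)
}
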