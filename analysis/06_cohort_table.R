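#!/usr/bin/env Rscript
# Stage 6: cohort group-comparison statistics.
#
# Recomputes the case/control characteristics table from the packaged
# printed summaries: pooled two-sample t-tests from (mean, sd, n) rows and
# two-tailed Fisher exact tests from 2x2 count rows. Writes
# results/cohort_report.tsv.

library(medipscan)

tab <- read_cohort_table(system.file("extdata", "cohort_table1.tsv",
                                     package = "medipscan"))
rep <- cohort_report(tab)
write_results(rep, file.path("results", "cohort_report.tsv"))

for (i in seq_len(nrow(rep))) {
  if (rep$test[i] == "pooled_t") {
    message(sprintf("%-34s t(%d) = %.2f, p = %.2f", rep$variable[i],
                    rep$df[i], rep$statistic[i], rep$p_value[i]))
  } else {
    message(sprintf("%-34s Fisher exact two-tailed p = %.3f",
                    rep$variable[i], rep$p_value[i]))
  }
}
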