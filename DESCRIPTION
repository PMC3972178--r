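Package: medipscan
Title: Differential Promoter Methylation Analysis for MeDIP Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide promoter DNA-methylation analysis of MeDIP
    promoter-tiling-array data for two-group designs. Computes per-probe
    empirical-Bayes moderated t-statistics on log2(MeDIP/input) ratios,
    aggregates probes to promoter-level differential-methylation calls by
    Wilcoxon rank-sum enrichment with Benjamini-Hochberg false discovery
    rates, scans the genome for clustered differential methylation
    (per-chromosome overrepresentation, fixed-width window enrichment,
    distance-dependent correlation of methylation differences), contrasts
    normalized CpG density between call groups, and reproduces cohort
    group-comparison statistics from printed summaries. Ships a synthetic
    data generator with planted effects so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
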