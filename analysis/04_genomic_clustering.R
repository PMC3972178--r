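#!/usr/bin/env Rscript
# Stage 4: spatial structure of the differential methylation.
#
# Three views: per-chromosome overrepresentation of called promoters (Fisher
# exact + BH), a 500 kb window enrichment scan of called probes, and the
# distance decay of correlation between per-probe methylation differences
# with a permutation null envelope. Writes the three tables under results/.

library(medipscan)

data_dir <- file.path("results", "data")
ann <- read_annotation(file.path(data_dir, "probes.bed"),
                       file.path(data_dir, "promoters.tsv"),
                       file.path(data_dir, "chrom.sizes"))
probe_res <- read.delim(file.path("results", "probe_results.tsv"))
prom <- read_promoter_results(file.path("results", "promoter_results.tsv"))
cfg <- analysis_config(seed = 20260919L, max_correlation_distance = 6e6,
                       distance_bin_width = 5e5, permutations = 200)

chrom <- chromosome_enrichment(prom, ann)
write_results(chrom, file.path("results", "chromosome_enrichment.tsv"))
message(sprintf("chromosome overrepresentation: min FDR %.3g on %s",
                min(chrom$fdr), chrom$chrom[which.min(chrom$fdr)]))

win <- window_scan(probe_res, ann, cfg)
write_results(win, file.path("results", "window_scan.tsv"))
enr <- enriched_windows(win, cfg$promoter_fdr_threshold)
write_results(enr, file.path("results", "enriched_windows.tsv"))
message(sprintf("window scan: %d of %d windows enriched at FDR <= %.2f",
                nrow(enr), nrow(win), cfg$promoter_fdr_threshold))

dc <- distance_correlation(probe_res, ann, cfg)
write_results(dc, file.path("results", "distance_correlation.tsv"))
sig <- dc$pearson_r > dc$null_upper & !is.na(dc$pearson_r)
message(sprintf("distance correlation exceeds the null envelope out to %.1f Mb",
                if (any(sig)) max(dc$bin_upper[sig]) / 1e6 else 0))
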