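#!/usr/bin/env Rscript
# Stage 5: normalized CpG density of the called promoters.
#
# Computes the observed/expected CpG dinucleotide density per promoter and
# contrasts the distributions between promoters gaining methylation in CPA,
# losing it, and the rest (two-sided rank-sum). The simulation planted a
# directional density link, so the up-vs-down contrast should be strongly
# significant. Writes results/density_contrasts.tsv.

library(medipscan)

data_dir <- file.path("results", "data")
ann <- read_annotation(file.path(data_dir, "probes.bed"),
                       file.path(data_dir, "promoters.tsv"),
                       file.path(data_dir, "chrom.sizes"))
prom <- read_promoter_results(file.path("results", "promoter_results.tsv"))

dens <- promoter_cpg_density(ann)
contrasts <- compare_density_groups(dens, prom)
write_results(contrasts, file.path("results", "density_contrasts.tsv"))

for (i in seq_len(nrow(contrasts))) {
  message(sprintf("%-12s median %.3f vs %.3f  p = %.3g",
                  contrasts$contrast[i], contrasts$median_a[i],
                  contrasts$median_b[i], contrasts$p_value[i]))
}
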