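#!/usr/bin/env Rscript
# Stage 1: simulate a MeDIP promoter-tiling dataset at desk scale.
#
# The generator mirrors the target study design -- 8 cases (CPA) vs 12
# controls, promoters tiled from -1000 to +250 bp around the TSS -- with 5%
# of promoters carrying a planted log2 effect of 1.0 inside 500 kb genomic
# blocks, so the downstream clustering stages have a recoverable ground
# truth. Writes the annotation, matrix, design and truth table under
# results/data/.

library(medipscan)

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- synthetic_config(
  n_chromosomes = 4, chromosome_length = 2e7,
  n_promoters = 2000, probes_per_promoter = c(3L, 6L),
  n_cpa = 8L, n_control = 12L,
  planted_fraction = 0.05, effect_log2 = 1.0, effect_sd = 0.2,
  noise_sd = 0.25, cluster_block_length = 5e5,
  cpg_density_link = "directional", seed = 20260919L
)

annotation <- generate_annotation(sc)
sim <- generate_matrix(sc, annotation)

write_annotation(annotation, out)
write_matrix(sim$matrix, out)
write_results(sim$truth, file.path(out, "truth.tsv"))
jsonlite::write_json(unclass(sc), file.path(out, "synthetic_config.json"),
                     auto_unbox = TRUE, pretty = TRUE)

message(sprintf("simulated %d probes tiling %d promoters (%d planted, %d samples)",
                nrow(annotation$probes), nrow(annotation$promoters),
                sum(sim$truth$planted), length(sim$matrix$sample_ids)))
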