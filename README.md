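# medipscan

Differential promoter DNA-methylation analysis for MeDIP promoter-tiling
arrays with a two-group design.

The scientific setting: methylated-DNA immunoprecipitation (MeDIP) hybridised
to promoter tiling arrays yields, per probe, a normalized log2(MeDIP/input)
ratio measuring local methylation. Probes tile each gene's promoter from
~1000 bp upstream to ~250 bp downstream of the transcription start site.
Given two groups of subjects — here a case group on a chronic physical
aggression (CPA) trajectory (n = 8) and matched controls (n = 12) — the
pipeline asks which promoters are differentially methylated, whether the
differences cluster along the genome, and how calls relate to promoter CpG
density. A synthetic-data generator reproduces the statistical structure of
such arrays (planted effects, spatial clustering, CpG-density covariates) so
every stage is testable without any external download.

## The statistics

**Probe level.** For probe *g* with pooled within-group variance *s²_g* on
*d* = n₁+n₂−2 degrees of freedom, an empirical-Bayes prior (d₀, s₀²) is
estimated across probes by moment-matching on log s²_g (digamma/trigamma
equations), and the moderated t-statistic is

    t̃_g = (x̄_g,CPA − x̄_g,ctl) / sqrt( s̃²_g (1/n₁ + 1/n₂) ),
    s̃²_g = (d₀ s₀² + d s²_g) / (d₀ + d),

referred to a t distribution on d₀+d df. A probe is *called* when its
(uncorrected) p ≤ 0.05 and |log2 fold difference| ≥ 0.25.

**Promoter level.** Each promoter's probes' t̃ are tested for enrichment
against all other probes on the array with one-sided Wilcoxon rank-sum tests
(both directions); the promoter p-value is the smaller side. Benjamini-
Hochberg FDR is computed across promoters, and a promoter is called
differentially methylated at FDR ≤ 0.2 with ≥ 1 probe called in its
direction (a stricter FDR ≤ 0.05 list is reported alongside).

**Genomic clustering.** Per-chromosome overrepresentation of called
promoters (one-sided Fisher exact, BH across chromosomes); a scan of fixed
non-overlapping 500 kb windows for enrichment of called probes per direction
(one-sided Fisher exact, BH across windows); and the distance decay of the
Pearson correlation between per-probe log2 fold differences, with Fisher-z
confidence intervals and a permutation null envelope.

**CpG density.** Normalized CpG density = observed CpG dinucleotide density
divided by the density expected from the C and G base densities; call groups
are contrasted by two-sided rank-sum tests.

**Cohort statistics.** Group-comparison statistics recomputed from printed
summaries: pooled two-sample t-tests from (mean, sd, n) and two-tailed
Fisher exact tests (point-probability method) from 2×2 counts.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on simulated
data (8 vs 12 samples, 2000 promoters, 5% planted effects of log2 = 1.0 in
500 kb blocks, directional CpG-density link):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_probe_stats.R
Rscript analysis/03_promoter_calls.R
Rscript analysis/04_genomic_clustering.R
Rscript analysis/05_cpg_density.R
Rscript analysis/06_cohort_table.R
```

which prints, stage by stage:

```
simulated 8979 probes tiling 2000 promoters (100 planted, 20 samples)
671 of 8979 probes pass the probe-level criteria (340 up, 331 down in CPA)
104 promoters called differentially methylated (52 up, 52 down in CPA); 100 at FDR <= 0.05
recovery vs truth: sensitivity 1.000, FDP 0.038, direction accuracy 1.000
chromosome overrepresentation: min FDR 4.79e-06 on chr4
window scan: 21 of 164 windows enriched at FDR <= 0.20
up_vs_down   median 0.770 vs 0.245  p = 2.45e-18
criminal_record_21y   Fisher exact two-tailed p = 0.019
attention_deficit_score_6_15y   t(18) = -0.81, p = 0.43
```

The planted 5% of promoters are recovered essentially completely at a false
discovery proportion well under the 0.2 FDR target, the planted 500 kb
blocks surface as enriched windows, and the planted density link shows up as
a strongly significant up-vs-down CpG-density contrast. All tables land
under `results/`. `run_pipeline()` performs the same sequence as one call
with a manifest for reproducibility.

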