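---
title: "Methods: differential promoter methylation from MeDIP tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential promoter methylation from MeDIP tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipscan)
```

## The measurement and the question

MeDIP-chip measures local DNA methylation as a per-probe log2 ratio of
immunoprecipitated (methylated) DNA over input DNA, on arrays whose probes
tile each promoter from 1000 bp upstream to 250 bp downstream of the
transcription start site (in transcription orientation; minus-strand
promoters extend to higher genomic coordinates on their upstream side).
Given two groups of subjects of unequal size (8 cases vs 12 controls in the
design this package targets), the analysis asks: which promoters differ in
methylation between groups, do the differences cluster along the genome, and
how do calls relate to promoter CpG density?

The package consumes normalized log2 ratios; array normalization, background
correction and batch adjustment are upstream and out of scope. Missing
values are rejected at load rather than imputed, because properly processed
arrays of this design are complete.

## Probe-level model

Each probe gets a two-group comparison with a *pooled* (Student) variance,
not Welch — the linear-model convention of empirical-Bayes microarray
analysis, and the convention implied by the pooled degrees of freedom in the
cohort table this package reproduces. With per-probe sample variance $s_g^2$
on $d = n_1 + n_2 - 2$ degrees of freedom, the hierarchical model
$s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_d / d$,
$1/\sigma_g^2 \sim \chi^2_{d_0} / (d_0 s_0^2)$ is fitted by method of
moments on $z_g = \log s_g^2$: with
$e_g = z_g - \psi(d/2) + \log(d/2)$, the excess of the sample variance of
$e_g$ over $\psi'(d/2)$ equals $\psi'(d_0/2)$, solved for $d_0$ by Newton
iteration (tolerance $10^{-8}$) with a bisection fallback; then
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$.

Numerical choices:

* Variances exactly zero are floored at $10^{-12}$ and excluded from prior
  fitting, so degenerate (e.g. constant synthetic) probes cannot poison the
  prior. This is a deliberate difference from limma, which winsorises them
  into the fit; the test suite compares against limma on zero-free inputs,
  where the two agree to $10^{-6}$.
* When the empirical dispersion of $\log s_g^2$ does not exceed its
  theoretical minimum, $d_0 = \infty$ and the prior variance is
  $\exp(\bar e)$; in the fully degenerate case where every variance is
  identical, that common value is returned exactly.
* The moderated statistic uses the posterior variance
  $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ — always between $s_g^2$
  and $s_0^2$ — and a t reference distribution on $d_0 + d$ df (standard
  normal when $d_0 = \infty$; the $d_0 \to 0$ limit recovers the ordinary
  pooled t-test exactly, which the tests assert to $10^{-9}$).

A probe is called differentially methylated at $p \le 0.05$ (deliberately
uncorrected — the multiplicity control lives at the promoter level) and
$|\text{log2 fold difference}| \ge 0.25$. Both thresholds are
`analysis_config()` parameters.

## Promoter-level aggregation

A promoter is scored by whether its probes' moderated t-statistics are
enriched toward either tail of the array-wide t distribution: one-sided
Wilcoxon rank-sum tests of the promoter's probes against **all other probes
on the array** (the background choice is the natural reading of
"enrichment" on a single array; it is also what makes the test cheap — the
combined sample of every test is the whole array, so one global midrank
vector serves all promoters). The promoter p-value is
$\min(p_\text{up}, p_\text{down})$ and the direction is the smaller side.

* Rank-sum p-values use the exact null distribution when the combined sample
  is $\le 25$ and tie-free, otherwise a normal approximation on midranks
  with tie correction and a 0.5 continuity correction. Exact enumeration is
  disabled when ties are present.
* Single-probe promoters are allowed (the rank-sum test is defined for
  $n = 1$) and flagged in the output.
* BH FDR is applied once to the pooled minima — one FDR column per promoter,
  no doubling. The per-promoter minimum of two one-sided p-values is not a
  calibrated two-sided p-value (under the null it is approximately uniform
  on $(0, \tfrac12)$); pooling the minima is nevertheless the default
  because it reproduces a single promoter-level FDR column, and the
  conservative alternative (Bonferroni-doubling the minimum before BH) is a
  config switch (`fdr_direction_pooling = "bonferroni"`). Null-calibration
  tests therefore check uniformity of the *one-sided* p-values.
* The final call requires FDR $\le 0.2$ **and** at least one probe called in
  the promoter's direction, so a promoter cannot be called on rank
  enrichment alone without a probe passing the effect-size criterion. A
  stricter FDR $\le 0.05$ flag is emitted alongside.

## Genomic clustering

*Chromosome level* uses the promoter as the unit: a one-sided Fisher exact
test (hypergeometric upper tail) per chromosome on called vs uncalled
promoters, BH across chromosomes, reported as $-\log_{10}(\text{FDR})$ bar
heights.

*Window scan* uses the probe as the unit: chromosomes are partitioned into
fixed non-overlapping windows (default 500 kb) anchored at coordinate 0 — a
fixed tiling, no sliding pass — and each window is tested per direction for
overrepresentation of called probes (one-sided Fisher exact), BH across all
windows per direction. Probes belong to the window containing their interval
midpoint. Enriched windows are reported with the gene promoters whose TSS
falls inside, in 1-based inclusive coordinates.

*Distance correlation* measures interdependence of methylation differences:
over all intra-chromosomal probe pairs separated by at most 10 Mb (midpoint
distance), the Pearson correlation of per-probe log2 fold differences is
computed per distance bin (default 500 kb wide), with a Fisher-z 95% CI
($\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$) and a null envelope
from 200 permutations of fold differences across probe positions within each
chromosome (2.5–97.5 percentiles). Pair counts per bin are capped by seeded
uniform subsampling (default $2 \times 10^6$) for tractability; per-bin sums
are computed by cumulative sums over bin-sorted pairs so permutations cost
no large allocations. Bins with fewer than 10 pairs, or with zero variance
(constant fold differences), report `NA`.

One calibration caveat is worth stating precisely: the permutation envelope
is exact for exchangeable (i.i.d.) fold differences, and the tests verify
nominal 5% exceedance in that case up to a binomial allowance. When the
signal itself is spatially correlated (planted blocks), the long-range
correlation *estimator* has extra sampling variance from block-level value
reuse that an i.i.d.-style permutation cannot see, so even where the true
correlation has vanished a small excess of envelope exceedances is expected.
The planted-structure tests therefore require the short-range bins to exceed
the envelope in every run but allow a binomial margin at long range.

## CpG density

Normalized CpG density is the observed CpG dinucleotide density divided by
the density expected from base composition:
$(\text{CpG}/(L-1)) / ((C/L)(G/L))$. The dinucleotide denominator is $L-1$
(the number of dinucleotide positions); a config switch uses $L$ instead,
and the two converge for promoter-scale $L$ (within 1% for $L \ge 1000$).
Density is undefined when $C = 0$ or $G = 0$; undefined promoters are
excluded from contrasts with their count reported. Sequence counting is
single-strand in genome orientation; CG is its own reverse complement, so
strand choice does not change the CpG count. `N` bases are excluded from
counts but retained in length — conservative toward undefined regions. Call
groups are contrasted (up vs rest, down vs rest, up vs down) with two-sided
rank-sum tests.

## Cohort statistics

Group comparisons are recomputed from printed summaries: Student pooled
two-sample t-tests from (mean, sd, n) — pooled rather than Welch, forced by
the printed degrees of freedom — and two-tailed Fisher exact tests from 2×2
counts using the point-probability method (sum of all tables with the same
margins whose probability is at most the observed one, relative tolerance
$1 + 10^{-7}$), with the sample odds ratio $ad/bc$. The packaged
transcription of the target cohort table reproduces the recomputable cells
exactly at printed precision; three of its printed entries (the
hyperactivity and anxiety Fisher p-values and the age-row t) are not
recoverable from their own printed summaries by the standard computations
and are reported as computed, not forced to the printed numbers.

## The synthetic-data generator

`synthetic_config()` defaults encode the target study design: 8 CPA vs 12
control samples, ~20,000 promoters on 22 chromosomes of 130 Mb (~5,700
windows of 500 kb genome-wide), 8–16 probes per promoter (~240k probes), a
5% planted fraction with mean |log2| effect 1.0 (SD 0.2), and per-probe
noise SD 0.25. The per-probe noise magnitude is not something the array
literature pins down for this design, so it was fixed once at a value giving
realistic probe-level t-statistics, and is config-exposed.

Probe values are generated directly as log2 ratios — no immunoprecipitation
enrichment/CpG-coupling model — because the analysis consumes log ratios;
that is the right abstraction level for testing it. A planted promoter's
shift (sign × Normal(effect, sd)) applies uniformly to all its probes in the
CPA samples only, matching the promoter-resolution claim the analysis makes.
When `cluster_block_length > 0`, planted promoters are drawn from randomly
placed genomic blocks and the sign is shared **within each block** (without
that, clustered planting would give the window scan and the distance
correlation no coherent ground truth). When
`cpg_density_link = "directional"`, the planted promoters above the
planted-set median density gain methylation in CPA and the rest lose it —
the strongest simple encoding of the density/direction association the
density contrast is meant to detect; the directional link takes precedence
over block-shared signs. CpG/C/G counts are drawn from a two-component
(island-like vs depleted) mixture so normalized density spans a realistic
bimodal range.

What the generator deliberately does not emulate: dye bias, spatial array
artifacts, batch effects, copy-number variation, correlated noise between
neighbouring probes, and any sequence-level realism beyond the density
summary counts. Passing tests therefore demonstrate statistical correctness
and calibration of the pipeline under its own model assumptions, not
robustness to those artifacts.

Determinism: every stochastic stage derives its own sub-seed from the single
config seed, so identical configs give byte-identical outputs end to end
(the pipeline manifest records md5 digests to verify this).

## Problem sizes and test design

The test suite and the acceptance script run the generator at desk scale —
typically 1000–2000 promoters with 3–6 probes each on four 20 Mb
chromosomes, 5–20 seeds per property — sizes chosen so the whole suite
completes in a few minutes while keeping every property statistically
well-powered (e.g. 50 planted promoters per recovery run, thousands of
probe pairs per distance bin). Statistical assertions on stochastic
quantities use explicit binomial or tolerance margins rather than exact
values, with seeds fixed for reproducibility.

## Known limitations

* The probe-level model assumes equal group variances per probe and
  independent probes; within-promoter probe correlation is absorbed only at
  the promoter aggregation step.
* The rank-sum background (all other probes) makes promoter p-values weakly
  dependent; BH is applied as if independent, the usual practice.
* The pooled-minimum promoter p-value is anticonservative before FDR
  thresholding (see above); the Bonferroni-doubling switch is provided.
* The permutation envelope of the distance correlation understates the
  long-range sampling variance of block-correlated signals (see above).
* No DMR segmentation (HMM/kernel) beyond fixed windows, no CpG-island
  calling beyond the continuous density statistic, and no pathway analysis.
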