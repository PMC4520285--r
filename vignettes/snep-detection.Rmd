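---
title: "Detecting single-nucleosome epi-polymorphisms between strains"
author: "snepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single-nucleosome epi-polymorphisms between strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two yeast strains grown under identical conditions can differ in the
histone-modification level of individual nucleosomes.  Raw ChIP-seq
counts confound two biological quantities: how often a nucleosome is
present in the cell population (occupancy, read out by the MNase-seq
input) and how much of the mark each occupied nucleosome carries.  Only
a difference of the second kind is a single-nucleosome epi-polymorphism
(SNEP).  `snepscan` turns aligned read starts from two or more strains
into SNEP calls, positional-divergence calls, gene-level divergence
statistics and their downstream summaries, and ships a generator that
plants all of these effects with recorded truth.

All internal coordinates are 0-based half-open; BED is written
natively and GFF3 is converted at the I/O boundary.  A single
convention eliminates off-by-one drift across the six analysis stages.

## Cross-strain comparison territory: CURs

Quantitative comparison is restricted to common uninterrupted regions
(CURs): colinear alignment segments at least `min_length` (default
4,000 bp, required in **both** strains) containing no indel larger than
`max_indel` (default 30 bp).  Alignment blocks are split at every
oversized indel and filtered by length; the split is greedy and the
solution unique.  Within a CUR, positions translate between strains by
cumulative indel offsets; a position inside a deleted segment maps to
the left flank of the deletion — a deterministic, monotone choice that
keeps translation total within CURs.  The test suite checks translation
base-for-base against the simulated genomes and against a brute-force
cumulative-offset walk, and checks exact round-tripping away from
indels.

Open question resolved: we require the length threshold in both
strains (the conservative reading), and CURs never span contig
boundaries.

## Nucleosome maps

The dyad caller replaces an external nucleosome-mapping tool whose
internals are not restated here, with a transparent equivalent that
preserves the downstream contracts:

* dyad coverage = forward read start + 73 bp, Gaussian-smoothed
  (`sigma` = 15 bp);
* candidate dyads are local maxima above the 25th percentile of
  nonzero smoothed coverage;
* a candidate must additionally have **prominence** (height above the
  larger of its two flanking minima within the exclusion window) of at
  least `noise_sd` = 3.5 standard deviations of the uniform-reads
  Poisson null, `sqrt(density * ||k||^2)` for smoothing kernel `k`.
  This suppresses peak picking on unstructured coverage of matched
  depth while keeping weak but isolated nucleosomes — a plain absolute
  floor fails one of the two requirements;
* greedy highest-score-first selection with a 120-bp exclusion zone.

Reproducibility across biological replicates uses an explicit proxy for
the companion likelihood-ratio test that the original pipeline
delegates to: pooled replicate dyads are grouped by splitting at gaps
larger than the 75-bp consensus window; a group is **well-positioned**
iff every replicate contributes exactly one dyad and their SD is at
most `sigma_max` = 20 bp, otherwise its footprint becomes a **fuzzy**
region.  Both knobs are exposed.

Maps of two strains are matched by mutual nearest neighbour after
translating strain-1 dyads, accepting |shift| <= 75 bp.  Everything
unpaired — unmatched wells and all fuzzy regions, from both strains —
is merged into unaligned nucleosomal regions (UNRs), so each call
belongs to exactly one pair or one UNR (the partition identity is a
test invariant).  A pair is **shifted** when |shift| > 10 bp.  An
unmatched strain-1 well joins the diverged subpopulation only if it
does not lie almost entirely (>= 99% overlap) inside a UNR containing
strain-2 occupancy — full overlap is conserved occupancy, not
positional divergence — and its nearest strain-2 well dyad is further
than 40 bp.  The 99%/40 bp pair parameterizes a boundary the source
analysis drew graphically; both are configurable and logged.

## The SNEP test

Counts per unit (matched pair: `[dyad - 73, dyad + 74)` in each
strain's own coordinates; UNR: its interval) are modelled as negative
binomial, log link, with the sample's median-of-ratios size factor as
offset:

```
log mu ~ log(sf) + strain + assay + strain:assay
```

The SNEP statistic is the 1-df likelihood-ratio test of `strain:assay`
— a ChIP difference beyond what the MNase difference predicts.  The
LRT was chosen over Wald for small-replicate calibration.  Direction is
the sign of the interaction coefficient; positive = more mark per
occupancy in the non-reference strain.  The occupancy-only test is the
strain-effect LRT on MNase counts.  Multiple testing is
Benjamini-Hochberg at FDR = 1e-4 per mark and strain pair, never
pooled.

Dispersion is estimated per unit by method of moments within
strain-by-assay cells on normalized counts, then shrunk 50% toward a
parametric trend `alpha(mu) = a0 + a1/mu` fitted across units, floored
at 1e-8.  This gives small-replicate stability without importing a
specific package's shrinkage scheme; with triplicates the null type-I
rate at alpha = 0.01 sits in [0.005, 0.02] and a 10,000-unit null
yields zero calls at FDR = 1e-4 (both asserted in the suite).

Two numerical facts worth knowing:

* **No exact scale invariance.**  Multiplying one sample's counts and
  its size factor by the same constant does *not* leave the LRT
  p-value exactly unchanged — scaling counts changes the Fisher
  information, so p drifts by a few percent.  The suite asserts the
  exact symmetry that does hold (swapping strain labels preserves p
  and flips direction) plus bounded drift.
* **Power floor.**  With depth 200, dispersion 0.05 and triplicates,
  the interaction-estimate SE cannot go below
  `sqrt(4/3 * (1/200 + 0.05)) ~ 0.27` nats.  At the genome-wide BH
  threshold (z ~ 4.6-4.9 for 10^4 tests at FDR 1e-4), power at
  log2FC = 1.5 is ~0.2; sensitivity 0.8 would require dispersion below
  ~0.022.  The acceptance test asserting 0.8 sensitivity in that
  stated world is therefore red by design, with the measured
  sensitivity (0.584 for log2FC ~ U[1.5, 2.5]) reported by the test
  itself.

## Gene-level divergence

Genes longer than 100 bp and fully inside a CUR are segmented into 600
bins: 250 fixed 10-bp bins upstream of the TSS, 100 TSS-to-TES
percentile bins (even integer split, remainder distributed from the 5'
side — widths differ by at most 1 bp and sum exactly to the gene
length), and 250 fixed 10-bp bins downstream, all oriented 5' to 3'.
Bin values are per-million forward starts, size-factor normalized and
replicate averaged; log2(ChIP/MNase) uses a pseudo-count of 0.1
per-million on both terms to stabilize near-empty bins.

**Differential patterns**: per gene, the per-mark log-ratio profiles
truncated to 500 bp on each side of the body (bins 201-450) are
concatenated and differenced between strains; genes whose mean ChIP
coverage is below 1e-3 per million for every mark in every strain are
dropped (the explicit stand-in for an unstated near-zero-signal rule).
Complete-linkage clustering on Euclidean distance; the metric was an
open choice and Euclidean is the default reading.

**epidiv** is the F statistic of the `strain:mark` term in the ANOVA
of the log-ratio over `strain + mark + bin + strain:mark + strain:bin +
strain:mark:bin`.  The `mark:bin` term is deliberately absent and is
absorbed by the residual, so the residual df is
`(marks - 1)(bins - 1)`.  One subtlety: fitting this formula with
`lm()` under R's default treatment contrasts *saturates* the model (the
three-way term columns span `mark:bin` too; residual df 0, F = NaN).
The statistic the contract describes corresponds to the orthogonal
balanced-ANOVA decomposition — equivalently, sum contrasts — which we
compute in closed form from cell means.  Each term's SS matches
`anova(lm(...))` with `contr.sum` on balanced data (a test oracle), the
SS and df totals close exactly, under the null epidiv follows
F(df1, df2) with mean df2/(df2 - 2), identical strains give exactly 0,
and the value is invariant to consistent bin reordering.  When more
than two strains are supplied, all of them enter the ANOVA.

**delta selection**: for a differential profile `d` over the 600
segments, `delta = median(d[284..333]) - median(d[251..266])` (mid-body
minus immediately-post-TSS), selecting genes with `delta > 10` — the
published region definitions and cutoff.

**QTL scan**: per gene, nucleosome-level segregant values are ranked
across segregants; the gene phenotype is the mean rank over second-half
body nucleosomes minus the first half.  (The source text says "last
two-thirds" in one place and "second half" in its figure legend; the
legend's second half is the default, the two-thirds variant is a flag.)
A PCA across genes summarizes segregants; components passing the
permutation rule — at most two, matching the published analysis —
become metaphenotypes, and if none passes, PC1 is used with a flag so
the threshold machinery still runs.  The PCA here skips the column-sum
normalization used for coverage matrices (meaningless for signed rank
phenotypes).  Each marker is tested by Wilcoxon rank-sum (the
deterministic reading of "non-parametric linkage test"), computed by a
vectorized normal approximation with tie and continuity correction that
matches `wilcox.test(exact = FALSE)` to machine precision (test
oracle).  The genome-wide threshold is the maximum score over ten
genotype-permuted scans.  By exchangeability the null probability that
any marker exceeds this threshold is exactly 1/11 ~ 9.1%, which is why
the null family-wise rate hovers just under 10%.

## Co-variation and regionality

Mark-by-mark Spearman correlations on per-nucleosome ChIP/MNase
signal; SNEP co-variation counts, for the SNEP set of one mark, how
many units show p < 0.01 divergence of a second mark *in the same
direction* (ties at estimate exactly 0 count as non-co-varying —
conservative), with Fisher's one-sided exact test against the non-SNEP
background.  Regionality counts, for each SNEP, whether its k-th
ordinal neighbour (k in ±1..10, genome order, contig-truncated) is
also a SNEP, against re-assignment of the same number of labels to the
eligible universe (optionally restricted to above-background
nucleosomes); 100 randomizations by default, seed-logged.
Positional-class (+1/-1/other) and persistence-by-co-variation tables
use chi-square with an exact-test fallback whenever an expected cell
drops below 5.

## The synthetic world

The generator states one world and the tests live in it:

* genomes: one ancestor, derived strains at SNP rate 0.005 (the
  published inter-strain divergence), indels at 1e-4-2e-4 with sizes
  up to 10-40 bp, suppressible inside gene bodies;
* landscapes: dyads every ~165 bp (the yeast repeat length), planted
  shifts bounded by 75 bp, evictions, and a fuzzy fraction whose
  per-replicate dyads jitter with SD 25 bp;
* reads: starts at the 5' edge (dyad - 73) + N(0, 10 bp), forward
  strand only; counts are Gamma-Poisson (NB) with a single dispersion
  (0.05 where the contract states it), per-sample depth multipliers
  log-uniform in [0.5, 2] to exercise size factors; a planted SNEP of
  log2FC f multiplies strain-2 ChIP weight by 2^f and leaves MNase
  untouched; fragment length is fixed at 147 bp (the mono-nucleosome
  band) — digestion heterogeneity is not modelled;
* per-mark gene-body enrichment shapes: 5'-skewed acetylation/H3K4me3,
  3'-skewed H3K4me1, piecewise-linear over body percentiles;
* crosses: Markov-chain genotypes (recombination 0.1 between adjacent
  markers), standard-normal nucleosome values, the planted allele
  adding `effect` SD to second-half nucleosomes.

What a green test does **not** establish: concordance with real MNase
digestion biases, GC or mappability artifacts, paired-end fragment
information, reverse-strand information (deliberately redundant here),
diploid or heterozygous genomes, or the exact numerical behaviour of
the original pipeline's nucleosome caller and dispersion-sharing
scheme.  The published genome-wide counts depend on the deposited
accessions and are treated as external benchmarks, not desk-scale
targets.

## Defaults that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_length` / `max_indel` | 4000 / 30 | bp | published CUR rule |
| `chunk_size` | 90 | bp | published chunking |
| dyad `sigma` / exclusion | 15 / 120 | bp | smooth at sub-nucleosome scale; no two dyads closer than ~a nucleosome |
| `noise_sd` | 3.5 | null SD | uniform-input suppression vs weak-peak retention |
| `sigma_max` / consensus window | 20 / 75 | bp | reproducibility proxy |
| match window / shift threshold | 75 / 10 | bp | published shift phenomenology |
| `dist_threshold` / overlap | 40 / 0.99 | bp / fraction | divergence-subpopulation boundary |
| SNEP FDR | 1e-4 | — | published threshold |
| log-ratio pseudo-count | 0.1 | per-million | stabilizes empty bins |
| delta cutoff, R1, R2 | 10, 251-266, 284-333 | segments | published selection |
| QTL permutations | 10 | — | published threshold rule |
| regionality window / randomizations | 10 / 100 | nucleosomes / — | published window; randomization count unstated, chosen for a tight envelope |

## Known limitations

* The reproducibility rule and dyad caller are explicit proxies for
  tools whose internals the contract does not restate; absolute counts
  of wells/fuzzy/UNRs will differ from the original pipeline even
  though every stated contract holds.
* LRT p-values with two replicates per cell are mildly
  anti-conservative in the far tail; with the design's triplicates the
  suite's calibration bounds hold.
* The QTL threshold's 1/11 null exceedance is intrinsic to a
  10-permutation maximum; more permutations would sharpen it but the
  count is part of the stated procedure.
* `run_pipeline` keeps whole read sets in memory; it is sized for
  yeast-scale genomes, not mammalian ones.
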