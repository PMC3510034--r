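---
title: "Inferring an RBP regulome from iCLIP: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring an RBP regulome from iCLIP: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipwalk)
```

clipwalk estimates the mRNA target set ("regulome") of an RNA-binding
protein (RBP) from iCLIP crosslink data, using a knockout genotype as a
binding-background control, and then asks what that target set does:
which functional annotations it clusters in, where down a ranked target
list the functional signal dissipates, and how target transcripts
redistribute across polysome fractions or subcellular compartments when
the protein is absent. The motivating application is a neuronal
CELF-family protein binding UGU-rich elements in 3'UTRs, but every stage
is generic.

This vignette records the statistical model behind each stage, the
tunable parameters and their defaults, the numerical conventions, and
what the synthetic-data generator does and does not emulate.

## Crosslink events and deduplication

iCLIP reads carry a 4-nt experimental barcode (library identity) and a
5-nt random barcode. Reads identical in (chromosome, start, strand,
experimental barcode, random barcode) are PCR copies of one cDNA;
`deduplicate()` collapses them and counts, at each genomic position, the
number of distinct barcode combinations — the number of unique
crosslink events. The crosslink nucleotide is one nt 5' of the read
start (truncation site chemistry): position `start - 1` on the plus
strand, `end` on the minus strand, in 0-based half-open coordinates.
Replicate libraries of a genotype are pooled by default; the
experimental barcode stays in the key, so pooling never merges cDNAs
from different libraries. `per_replicate = TRUE` keeps replicates apart.

Events are classified against the annotation under the fixed priority
hierarchy ncRNA > 3'UTR > 5'UTR > ORF > intron > antisense > intergenic:
of all same-strand features covering the position the highest-priority
label wins; a position covered only by an opposite-strand gene is
antisense. Per-class enrichment is the event fraction (each event
weighted by its cDNA count) over the fraction of the stranded genome the
class covers.

## Cluster calling and the permutation FDR

Crosslink-site significance is assessed per gene against a uniform
placement null: the gene's cDNAs are dropped uniformly at random over
the gene span and per-position heights re-tabulated, `n_perm` times
(default 100). For a height threshold h,

FDR(h) = (mean permuted positions with height >= h) /
         (observed positions with height >= h),

and the working threshold is the smallest h with FDR(h) at or below
`fdr_level` (default 0.05). Heights of 1 are never significant under
this null — the expected number of occupied positions is at least ~63%
of the observed count for any gene longer than its read count — so the
search starts at h = 2, which is an optimization, not an approximation.

Significant sites within 15 nt merge into one cluster. Each cluster is
summarized by its count-weighted centre of mass, rounded half up to an
integer nucleotide so windows are deterministic, and a 31-nt window
(15 nt each side). The window sum counts all cDNAs in the window,
significant or not.

## Occupancy and target ranking

Cluster occupancy is `(window_sum / library_total) / FPKM`: the window's
share of the library, corrected for how abundant the transcript is.
Occupancy is invariant to uniform library scaling and halves when FPKM
doubles. Any positive per-gene expression table can stand in for FPKM;
genes with missing or non-positive expression are excluded.

A gene's wildtype occupancy is that of its highest-count cluster
(`window_sum`, ties to the leftmost window — count, not occupancy,
because the highest-count cluster is the best-supported binding site).
From it the highest cluster occupancy of the same gene in the null
libraries is subtracted; ranking is by this difference, descending, with
ties broken by wildtype occupancy then gene id. The ranking universe is
restricted to expressed genes (default: at least 10 normalized reads).
Pooling choices (replicates pooled per genotype; pooled null rather than
max-over-replicates) are defaults with flags, since either reading is
defensible.

## Pentamer z-scores

Sequence preference around crosslink sites is quantified per 5-mer as

z = (observed occurrence − mean occurrence over shuffled controls) /
    sd of occurrence over shuffled controls,

with overlapping occurrences summed over strand-aware windows of
half-width 10 or 30 nt centred on the crosslink nucleotide (windows
truncated at contig ends are dropped). Controls are per-window
mononucleotide shuffles — the simplest null that preserves each window's
exact base composition; a dinucleotide shuffle would additionally
preserve stacking context but also absorb part of the signal being
tested, so it is not the default. When the control sd is 0, z is 0 if
the observation equals the control mean and a +/-Inf sentinel otherwise;
sentinels should be filtered before ranking contrasts on small window
sets. By default z-scores are computed over sites inside significant
clusters (the better-attested contacts); the all-sites alternative is a
matter of passing those events instead. Genotype contrast is the
z difference per pentamer, wildtype minus null.

## Walk-down threshold estimation

The ranked list is split serially into `floor(N / group_size)` groups
(the remainder joins the last group, matching the published arithmetic
in which 40 groups of 357 cover 14,280 of 14,288 genes, and 15 groups of
204 cover 3,060 of 3,222 — the leftover genes are not dropped). Each
group is scored for term over-representation independently against the
full ranking universe: one-sided hypergeometric p per term with BH
correction, `n_clusters` = significant terms at `alpha`, `min_p` =
smallest raw p. This in-package scorer replaces interactive annotation
servers; the walk-down logic, not any particular enrichment backend, is
the method. Two cumulative curves result: significant-term counts and
−log10 min p. Controls shuffle the gene order uniformly (`n_perm`,
default 100 — studies of this design report 50 or 100 rounds; the
larger is the default) and
average the curves pointwise.

The inflection is found by a two-segment piecewise-linear fit: every
breakpoint with at least two groups per side is scored by total squared
error, the best breakpoint must flatten (second slope smaller than the
first beyond a relative tolerance of 1e-8, so exactly linear or constant
curves return no threshold), and SSE comparisons carry a small absolute
tolerance so floating-point noise cannot move a tie. Scanning right to
left makes an exact kink resolve to the kink group itself. The threshold
is `breakpoint group x group_size` ranks. The same machinery accepts a
per-gene differential-expression indicator in place of enrichment
(`expression_corroboration()`), with group means accumulated instead.

## Genotype-by-treatment interaction models

Counts are upper-quartile normalized: each sample divided by the 75th
percentile of its nonzero values (linear-interpolation quantile), then
rescaled by the mean upper quartile. Each gene's values are replaced by
normal scores of their mid-ranks, `qnorm((r − 0.5)/n)` with ties
averaged, and a two-way fixed-effects ANOVA (treatment + genotype +
interaction) is fitted per gene. The F statistics come from sequential
model comparison computed via QR projections on the whole gene-by-sample
matrix at once; on balanced designs these equal the classical sums of
squares, and the tests verify exact agreement with `anova(lm())` and a
hand-worked table. The two treatment contrasts of the motivating study
(monosome vs polysome; cell body vs neuropil) are run as separate
two-level designs, with rank transformation within each experiment.

The interaction p is permutation-based: sample labels are shuffled
within the design (the same shuffle applied to all genes per round),
interaction Fs recomputed, and all rounds and genes pooled into one null
distribution. Pooling buys resolution at small n; it assumes gene
exchangeability under the null, which the rank transform makes
reasonable.

One capability bound is worth stating plainly. With 12 samples the
per-gene normal scores are fixed by ranks alone, so once an effect fully
separates the three samples of one design cell the interaction F cannot
grow further; for a one-cell shift the ceiling sits essentially at the
5% critical value of F(1,8). Detection of such effects at 3 replicates
per cell therefore has power of roughly 0.4 no matter how large the
planted effect or how small the noise — a property of rank-based scores
at this design size, not of the implementation. Crossover-type
interactions do not hit this ceiling. Untransformed analysis
(`transform = FALSE`) is available when parametric assumptions are
acceptable.

Downstream, `rank_association()` relates interaction strength to the
iCLIP ranking (rank regression of the F rank on top-k target status,
plus a Spearman correlation; the published second-level model is not
fully specified, so this reconstruction is labelled as such, not claimed
equivalent), and splits the top-k targets at the median F into equal
high/low sets (odd k: extra gene to low). `delta_log_p()` compares term
enrichment between those sets on the log10 scale; negative values mean
more significant in the high set. `direction_table()` classifies
category genes per genotype by the treatment-B/treatment-A ratio of mean
normalized expression (ratios exactly 1 are excluded, as the contingency
columns are strictly >1 / <1) and applies a two-sided Fisher exact test
(conditional point-probability method, the convention when sidedness is
unstated) with the sample odds ratio, flagged infinite at a zero
off-diagonal cell. `ddct_fold_change()` implements qPCR fold change as
2^ddCt with Ct averaged over triplicates and the sign convention that
positive ddCt means up in the experimental genotype.

## The synthetic-data generator

`sim_config()` fixes the study conditions; all generators are
deterministic given the seed, with per-generator sub-seeds derived from
it so wildtype and null libraries get distinct but reproducible streams.

What it emulates: one chromosome with genes laid out in transcription
order (5'UTR, ORF, intron, 3'UTR; 10% cv around configured mean lengths,
defaults 150/1200/800/600 nt), intergenic gaps (mean 500 nt), a fraction
of genes with overlapping antisense ncRNA decoys (10%) so the hierarchy
is exercised; log-normal expression (meanlog 3, sdlog 1); background
crosslinks both genome-wide and expression-coupled along gene bodies
(0.01/nt), plus wildtype-only signal at UGU-core motif sites planted in
target 3'UTRs (3 sites per target, 0.15 crosslinks per 3'UTR nt scaled
by relative expression); PCR duplication at rate 0.2 with 5-nt random
barcodes; negative-binomial counts with dispersion 0.05 — the standard
magnitude for bulk RNA-seq on inbred mouse tissue — around log-normal
baselines, with a log2 interaction effect planted in the null x
treatment-B cell of a target subset; and term sets half-concentrated in
the planted targets so top-of-ranking enrichment exists by construction.
Rates were chosen once as representative of a brain iCLIP library of a
few million usable reads scaled to desk size; none is fitted to data.

What it does not emulate: realistic read sequences or qualities,
alignment artefacts, spliced reads, isoform structure, chromatin or
mappability biases, and any correlation structure between genes beyond
the planted effects. Passing tests on this generator demonstrate that
the inference chain recovers planted structure under its own model
assumptions — calibrated cluster FDR, near-perfect target AUC, a
walk-down threshold at the planted target count — not that those
operating characteristics transfer to any particular real library.

## Problem sizes used in the checks

The test suite and the acceptance script run the full chain at the
published ranking scale (14,288 genes, 2,000 planted targets, groups of
357), cluster-FDR calibration on 50 uniform genes, ANOVA calibration and
power on 1,000 genes with 3 replicates per cell, and exact-agreement
checks of the Fisher and hypergeometric paths against enumeration
oracles. Smaller configurations (tens to hundreds of genes) cover the
unit-level contracts.
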