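# clipwalk

Inference of an RNA-binding protein's mRNA target set (its *regulome*)
from iCLIP crosslink data, with downstream transcriptomic models of what
the protein does to its targets. The package is aimed at analysts of
protein–RNA interaction studies that pair a wildtype iCLIP library with
a knockout-genotype background library — the motivating case is a
neuronal CELF-family protein binding UGU-rich 3'UTR elements — and at
method developers who want a fully synthetic, seeded test bed for this
class of pipeline.

## What it computes

**iCLIP core.** Reads carrying 4-nt experimental and 5-nt random
barcodes are collapsed to unique crosslink events (PCR deduplication);
the crosslink nucleotide is one nt 5' of the read start. Events are
classified by the segment hierarchy
ncRNA > 3'UTR > 5'UTR > ORF > intron > antisense > intergenic.
Per gene, crosslink sites are tested against a uniform within-gene
placement null: the count threshold is the smallest height *h* with

    FDR(h) = E[permuted sites ≥ h] / #{observed sites ≥ h} ≤ α,

significant sites within 15 nt merge into clusters, and each cluster is
scored over a 31-nt window centred on its count-weighted centre of mass.
Cluster occupancy is

    occupancy = (window_sum / library_total) / FPKM,

and genes are ranked by wildtype occupancy at the highest-count cluster
minus the best null-genotype cluster occupancy in the same gene.

**Motif analysis.** Per-pentamer z-scores,
`z = (obs − mean_shuffled) / sd_shuffled`, over strand-aware windows
(half-width 10 or 30 nt) against composition-preserving mononucleotide
shuffles, with a wildtype-minus-null contrast.

**Walk-down threshold.** The ranking is split into serial groups
(e.g. 357 genes), each scored by hypergeometric term over-representation
with BH correction; cumulative significant-term and −log10 min-p curves
are compared with permuted-ranking controls, and a two-segment
piecewise-linear fit locates the inflection where functional signal
dissipates — the estimated binding threshold in rank units.

**Differential models.** Upper-quartile normalization; per-gene
rank-based normal scores `Φ⁻¹((r − 0.5)/n)`; two-way
genotype-by-treatment interaction ANOVA with a pooled
sample-permutation null; rank association between interaction strength
and iCLIP rank with a median F split; Δ log10 p term comparisons
between the high and low halves; Fisher-exact direction-of-effect
contingency tables; and qPCR `2^ΔΔCt` fold changes.

**Synthetic data.** `sim_config()` + `simulate_study()` generate
annotation, chromosome sequence with planted UGU-core motif sites,
wildtype/null iCLIP libraries with PCR duplicates, negative-binomial
count matrices with planted interaction effects, and target-concentrated
term sets — everything needed to exercise the chain end to end, byte
reproducible under a seed.

## Worked example

```r
library(clipwalk)

cfg <- sim_config(n_genes = 300, n_targets = 60, seed = 13)
sim <- simulate_study(cfg)

ev_wt   <- deduplicate(sim$reads_wt)
ev_null <- deduplicate(sim$reads_null)
segment_enrichment(assign_segment(ev_wt, sim$ann), sim$ann)

cl_wt   <- call_clusters_all(ev_wt,   sim$ann, n_perm = 100, seed = 1)
cl_null <- call_clusters_all(ev_null, sim$ann, n_perm = 100, seed = 2)
occ_wt   <- occupancy(cl_wt,   sum(ev_wt$count),   sim$fpkm)
occ_null <- occupancy(cl_null, sum(ev_null$count), sim$fpkm)

genes <- sim$ann$genes$gene_id[!startsWith(sim$ann$genes$gene_id, "NC")]
rk <- rank_genes(occ_wt, occ_null, genes)
head(rk, 5)

wc <- walk_down(rk, 20, sim$terms)
detect_inflection(wc)$threshold_rank
```

Output (abridged):

```
        label n_events enrichment
1:      ncRNA     1032  1.6242661
2:       3UTR    14905  3.5460564
3:       5UTR     1290  1.2375854
4:        ORF    10308  1.2188675
5:     intron     7112  1.2668877
6:  antisense     7969  0.4265823
7: intergenic     3038  0.4326897

   gene_id       wt_occ null_occ        score  rank
1:  G00003 1.346125e-04        0 1.346125e-04     1
2:  G00124 8.597743e-05        0 8.597743e-05     2
3:  G00167 7.028283e-05        0 7.028283e-05     3
4:  G00173 6.779169e-05        0 6.779169e-05     4
5:  G00278 6.629443e-05        0 6.629443e-05     5

threshold_rank: 60
```

The wildtype library is ~3.5-fold enriched for 3'UTR crosslinks over
genomic expectation (the planted binding territory), 172 wildtype vs 5
null clusters are called, 59 of the top 60 ranks are planted targets,
and the walk-down inflection lands at rank 60 — exactly the planted
target count.

A thin command-line wrapper over the same functions is installed at
`inst/cli/clipwalk.R` (subcommands `simulate`, `dedup`, `clusters`,
`occupancy`, `rank`, `motif`, `walkdown`, `interaction`, `direction`,
`ddct`).

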