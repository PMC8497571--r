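# bipair

Strand-aware downstream analysis of nascent-RNA (4sU-seq), total RNA-seq
and Pol II ChIP-seq experiments, centred on one question: **are the genes
that respond to a perturbation of promoter-proximal Pol II pausing (such
as depletion of the 7SK snRNP) enriched for highly expressed,
bidirectionally transcribed gene pairs?**

Bidirectional (divergent) promoters drive head-to-head gene pairs whose
TSSs lie less than 1 kb apart. `bipair` provides the pieces needed to
make and test that claim from standard inputs (GTF annotation, DE result
tables, stranded coverage, peak sets):

* **Gene-pair annotation** — for every gene, the nearest neighbour in
  each direction x orientation category (upstream/downstream x
  sense/antisense), by gap distance between gene spans, with
  within-threshold flags (`annotate_pairs()`, default threshold 1 kb).
* **Bidirectional-promoter calls** — opposite-strand initiation signal
  (CAGE peaks or stranded coverage) within 100 nt upstream of the TSS
  (`call_bidirectional()`).
* **Pausing and metagene statistics** — the travelling ratio
  TR = signal in [TSS, TSS+250) / signal in [TSS+250, TES]
  (`pausing_index()`); scaled-region and reference-point metagene
  matrices (`metagene_scaled()`, `metagene_refpoint()`); and a
  reference-gene library normalization that subtracts the unchanged-gene
  body baseline and rescales by their TSS ± 1 kb mean
  (`normalize_polII()`, reference from `select_unchanged_genes()`).
* **Intron/exon coverage ratios** — median-of-ratios size factors from
  exonic counts, per-gene mean intron / mean exon coverage with a CPM > 20
  floor and the degenerate-value substitutions 1 (no exon counts) and
  0.001 ((nearly) no intron counts) (`size_factors()`,
  `intron_exon_ratio()`, `ratio_vs_fc()`).
* **Enrichment statistics** — DE classes (padj < 0.05, |log2FC| > 0.3,
  strict), fold enrichment with a two-sided Fisher's exact test
  (`fold_enrichment()`), 99.9% resampling null bands from 10,000 random
  gene subsets (`resample_null_band()`), expression ECDFs with KS
  distances (`expression_ecdf()`).
* **A synthetic genome with ground truth** — tunable divergent-pair
  fraction and TSS–TSS distances, log-normal expression and travelling
  ratios, planted antisense signal, intron retention and a knock-down
  that represses high-expressed divergent genes (`sim_config()`,
  `simulate_annotation()`, `simulate_coverage()`, `simulate_de_table()`),
  plus an end-to-end driver (`run_pipeline()`).

All intervals are 1-based closed `GRanges`; GTF/BED/bedGraph I/O goes
through rtracklayer. See the vignette
(`vignettes/bidirectional-pairs.Rmd`) for the methods in full.

## Worked example

Simulate the knock-down study, call DE classes, and test whether the
repressed genes are enriched for upstream antisense partners:

```r
library(bipair)

cfg  <- sim_config(n_genes = 600, n_chromosomes = 12, depth = 8e5, seed = 1)
sim  <- simulate_annotation(cfg)
ctrl <- simulate_coverage(sim, "control",   n_reps = 2)
kd   <- simulate_coverage(sim, "knockdown", n_reps = 2)

de <- classify_de(simulate_de_table(ctrl$exon_counts, kd$exon_counts))
attr(de, "class_counts")
#>        up      down unchanged
#>         0        83       517

down  <- de$gene_id[!is.na(de$class) & de$class == "down"]
pairs <- annotate_pairs(sim$ann)
round(pair_frequencies(pairs), 3)          # all genes
#>   upstream_antisense downstream_antisense       upstream_sense     downstream_sense
#>                  0.3                  0.0                  0.0                  0.0
round(pair_frequencies(pairs, down), 3)    # repressed genes
#>   upstream_antisense downstream_antisense       upstream_sense     downstream_sense
#>                    1                    0                    0                    0

fe <- fold_enrichment(pairs, down, "upstream_antisense")
fe$fold; fe$p_value
#> [1] 3.333333
#> [1] 2.08e-51
```

Every one of the 83 repressed genes has a head-to-head partner within
1 kb, against a 30% background rate — a 3.3-fold enrichment (Fisher
p ≈ 2e-51). That is the planted structure: the simulated knock-down
represses high-expressed divergent genes. The travelling ratios
recovered from the same coverage have median ≈ 2.9, matching the planted
log-normal around 3:

```r
tr <- fragments_to_coverage(ctrl$fragments[[1]], sim$seqlengths)
pt <- pausing_index(tr, sim$ann)
summary(pt$travelling_ratio[is.finite(pt$travelling_ratio)])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.518   2.185   2.939   3.402   4.267  16.708
```

The same functions apply unchanged to real inputs: a Gencode GTF via
`read_gene_annotation()`, DESeq2 result tables via `read_de_table()`,
stranded bedGraphs via `read_bedgraph_pair()`, and CAGE/histone peak BED
files imported with rtracklayer.

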