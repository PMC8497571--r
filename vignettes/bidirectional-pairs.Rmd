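---
title: "Analysing bidirectional gene pairs, Pol II pausing and nascent transcription with bipair"
author: "bipair authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing bidirectional gene pairs with bipair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipair)
```

## Scientific background

Promoter-proximal pausing of RNA polymerase II is a widespread regulatory
step: Pol II initiates, transcribes a short distance past the TSS, and
stalls until pause release commits it to productive elongation. The 7SK
snRNP — a ribonucleoprotein scaffolded by the noncoding RNA RN7SK —
sequesters the P-TEFb kinase that triggers pause release, and perturbing it
changes how transcription is distributed along genes. A recurring
observation in such perturbations is that the genes most sensitive to 7SK
loss are *highly expressed genes transcribed from bidirectional
(divergent) promoters*: head-to-head gene pairs whose TSSs lie less than
1 kb apart and that initiate transcription in opposite directions from a
shared regulatory region.

`bipair` implements the downstream computational analysis needed to make
and test that kind of claim from standard sequencing readouts:

* strand-aware annotation of each gene's nearest neighbour in the four
  direction x orientation categories (upstream/downstream x
  sense/antisense), with the fraction of genes having a partner within a
  distance threshold;
* bidirectional-promoter calls from opposite-strand initiation signal
  (CAGE peaks or stranded nascent-RNA coverage) near the TSS;
* Pol II pausing statistics (travelling ratio) and metagene matrices with
  a reference-gene library normalization;
* intron/exon coverage ratios as an intron-retention readout;
* enrichment statistics: DE classes, fold enrichment with Fisher's exact
  test, and resampling null bands for profile comparisons.

Every stage can be exercised against a synthetic genome with known ground
truth, so the statistical behaviour of the whole chain is testable without
any external download.

## Coordinate conventions

All intervals are 1-based closed `GRanges`, the native Bioconductor
convention; this keeps the package interoperable with the rest of the
GenomicRanges ecosystem and delegates coordinate conversion to
`rtracklayer` at the GTF/BED/bedGraph boundary (GTF is 1-based inclusive
and passes through unchanged; BED-family formats are converted by the
importer). All strand-dependent quantities (TSS, promoter windows,
metagene orientation, pausing windows) are computed in transcription
orientation.

## Gene pairs and bidirectionality

`annotate_pairs()` reports, for every gene, the nearest gene in each of
the four categories. Distance is the genomic **gap between gene spans**
(abutting or overlapping spans count as distance 0, and an overlapping
neighbour qualifies in both directions). Gap distance handles all four
categories uniformly and, for non-overlapping head-to-head pairs, tracks
the TSS-TSS distance up to each gene's span. The within-threshold flag
uses a strict inequality (`distance < pair_max_dist`, default 1000 bp,
i.e. "less than 1 kb away"); ties between equidistant candidates break by
the lexicographically smaller gene id so the output is deterministic.

`call_bidirectional()` flags a gene when initiation signal lies on the
*opposite* strand within `antisense_window` (default 100 nt) upstream of
its TSS — the region a divergent partner transcript initiates into.
Evidence can be a stranded peak set (e.g. CAGE) or summed opposite-strand
coverage above a configurable floor (default: any signal). A centred
+/- window variant is available for sensitivity analysis.

`fold_enrichment()` compares the fraction of a DE class having a partner
in a category against the same fraction in the gene universe and tests
the 2x2 table (class vs rest x partner status) with a two-sided Fisher's
exact test, the standard convention of summing all tables no more probable
than the observed one. No multiple-testing correction is applied across
the four categories; p-values are per category.

`pair_coregulation()` regresses partner log2 fold-changes on focal-gene
log2 fold-changes by OLS, stratified by partner mean expression above or
below a floor, and tests slope = 0 with the usual two-sided t-test;
strata with fewer than three pairs are flagged rather than fitted.

## Pausing and metagene statistics

The travelling ratio (pausing index) of `pausing_index()` is the signal
in the promoter-proximal window `[TSS, TSS + 250)` (transcription
orientation) divided by the signal over the remaining transcribed region
to the TES. Genes not longer than the window are excluded with a message;
genes with zero body signal are reported with `TR = Inf` and a flag, not
silently dropped. The ratio is invariant to global rescaling of the
track, so raw and per-million tracks give identical values.

`metagene_scaled()` emits per-gene vectors over a 1000 bp upstream flank,
the first 1000 bp of the gene, the remaining body linearly rescaled to
500 bp, the final 500 bp, and a 500 bp downstream flank, binned at 10 bp
(350 columns); minus-strand rows are reversed so the TSS is always on the
left. Body rescaling is linear interpolation onto 500 equally spaced
points, which preserves constant signal exactly and makes the operation
linear in the track. Bin values are means of covered bases. Genes shorter
than the two unscaled segments are dropped with a message.

`normalize_polII()` removes ChIP-efficiency differences between libraries
using a reference set of high-expressed genes unchanged between
conditions: it subtracts the mean baseline over the reference genes'
*scaled-body* bins — exactly the bins excluding the unscaled TSS- and
TES-proximal segments — and then divides by the mean of the subtracted
signal over TSS +/- 1 kb of the same genes. The TSS +/- 1 kb mean is
computed per library after subtraction. Two fixed points pin the
behaviour down: the reference TSS +/- 1 kb mean is exactly 1 after
normalization, and affine (scale + offset) differences between libraries
cancel exactly; renormalizing with the same reference is the identity.

`select_unchanged_genes()` supplies the reference set: genes with a point
estimate `|log2FC| < 0.3` *and* `padj > 0.5` under the standard test,
ranked by mean expression, top *n* (default 199). This is an
equivalence-style approximation of a dedicated analysis under the
shifted null hypothesis `|log2FC| > 0.3`; re-fitting a shifted-null Wald
test is out of scope here, and the approximation errs on the side of
selecting clearly unchanged, well-measured genes.

## Intron/exon ratios

`size_factors()` computes median-of-ratios size factors from exonic
counts (via DESeq2's implementation of the formula).
`intron_exon_ratio()` then forms, per gene, mean intron coverage divided
by mean exon coverage, where mean coverage is the size-factor-normalized
count divided by the total feature length (exon union and derived introns
from `feature_lengths()`). Only high-expressed genes with mean counts per
million above 20 enter; the CPM is computed on combined exon + intron
counts, since an exon-only CPM could never admit the "no exon counts"
degenerate case the substitution rules are defined for. Degenerate ratios
are substituted and flagged: no exon counts gives 1; zero intron counts
or a computed ratio below 0.001 gives 0.001. `ratio_vs_fc()` couples
per-gene log2 ratio changes between conditions to expression log2
fold-changes with a Spearman correlation — a negative correlation is the
intron-retention signature of repressed genes.

## DE classes and null bands

`classify_de()` applies the class thresholds with strict inequalities:
`up` means `log2FC > 0.3` and `padj < 0.05`, `down` the mirror image,
everything else `unchanged`; genes with missing `padj` stay unclassified.

`resample_null_band()` draws 10,000 random gene subsets of exactly the
class size (without replacement), takes each subset's column-mean
profile, and reports per-column nearest-rank percentiles at the 0.05th
and 99.95th position (a 99.9% band). Nearest-rank interpolation keeps the
band deterministic across platforms; the band is bit-reproducible under a
fixed seed, collapses to the global mean when the subset is all rows, and
nests monotonically in the confidence level.

## The synthetic genome

`simulate_annotation()` and `simulate_coverage()` generate the study
conditions the analyses assume, with a full per-gene truth table:

* a configurable fraction of head-to-head pairs (default 0.3) at
  log-uniform TSS-TSS distances of 100-900 bp, all below the 1 kb
  threshold; all other genes are isolated by 3-8 kb intergenic gaps so no
  accidental sub-kilobase pairs arise;
* gene lengths uniform on 2-6 kb with 1-3 exons and, with probability
  0.3, a second transcript skipping the first exon (exercising the
  "exclusively first" exon logic);
* log-normal expression (meanlog = log 100, sdlog = 1) and log-normal
  travelling ratios (meanlog = log 3, sdlog = 0.5, typical of paused
  genes); reads are fragment intervals (50 nt), with the promoter-window
  read share chosen to realize each gene's TR and the intron read share
  chosen to realize its intron/exon coverage ratio (log-normal around
  0.1);
* opposite-strand initiation reads in the 100 nt window upstream of the
  TSS for 90% of divergent genes and 5% of background genes;
* a knock-down condition that represses divergent genes above the median
  expression by log2FC ~ N(-1, 0.3) and multiplies the intron ratio of
  repressed genes by 1.5 (intron retention).

`simulate_de_table()` provides the consumed DE table: log2 fold-changes
of size-factor-normalized means (pseudocount 0.5) with an exact
conditional binomial test on summed counts — the null success probability
uses size-factor shares so that compositional shifts from strong planted
repression do not bias null genes — and Benjamini-Hochberg adjustment. It
is a simple stand-in adequate for the simulated Poisson counts; it makes
no claim to reproduce a negative-binomial DE model on real, overdispersed
data.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: mappability and GC artefacts, read
mis-assignment between overlapping genes, fragment-length variation,
biological overdispersion beyond Poisson noise, annotation errors, and
enhancer RNAs. The generator verifies the *statistical machinery*; the
headline genome-scale annotation counts and enrichment folds on the real
datasets require the corresponding public inputs (a Gencode v19 GTF and
the published expression tables), to which the same functions apply
unchanged.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at sizes chosen
to make every stochastic check well-powered while keeping a full run in
the minutes range: 600 genes x 2 replicates x 2 conditions at 8 x 10^5
reads per sample for the end-to-end knock-down study; 2000 genes for the
planted-enrichment recovery (100 seeds in the test suite); 300 genes at
roughly 30x base coverage for travelling-ratio recovery; 10,000 resampled
subsets for the null band, exactly as the band is defined.

Other numerical decisions, all deterministic: ties in neighbour search
and in unchanged-gene ranking break by gene id; partial trailing metagene
bins average over their actual width; windows clipped at chromosome
boundaries are zero-padded (reference-point) or trimmed (promoters);
Fisher's test uses the two-sided summation convention; the travelling
ratio of an empty gene body is `Inf` with a flag.

## Known limitations

* Neighbour search is restricted to the supplied gene universe
  (protein-coding by default); pairs with non-coding partners are out of
  scope.
* The DE stand-in is Poisson-exact, not negative-binomial; on real data
  supply a DESeq2/edgeR results table to `classify_de()` instead.
* GTF only (Gencode attribute dialect); GFF3 is not parsed.
* Single-end fragment extension is a fixed length; no fragment-size
  modelling.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 600, n_chromosomes = 12, depth = 8e5, seed = 1)
sim  <- simulate_annotation(cfg)
ctrl <- simulate_coverage(sim, "control", n_reps = 2)
kd   <- simulate_coverage(sim, "knockdown", n_reps = 2)

de    <- classify_de(simulate_de_table(ctrl$exon_counts, kd$exon_counts))
down  <- de$gene_id[!is.na(de$class) & de$class == "down"]
pairs <- annotate_pairs(sim$ann)
fold_enrichment(pairs, down, "upstream_antisense")

## or, file-based and end to end:
dir <- tempfile(); out <- tempfile()
write_dataset(sim, ctrl, kd, dir)
res <- run_pipeline(dir, out)
```
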