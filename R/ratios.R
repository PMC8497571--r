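#' Median-of-ratios size factors from exonic counts
#'
#' Per-sample scaling factors computed with the median-of-ratios method on
#' the exonic count matrix: for sample j, the median over genes of
#' count_gj divided by the gene's geometric mean across samples, genes with
#' any zero count excluded from the median. Computed via
#' [DESeq2::estimateSizeFactorsForMatrix()].
#'
#' @param exon_counts integer matrix, genes x samples (>= 2 samples).
#' @return named numeric vector of size factors (one per column).
#' @export
size_factors <- function(exon_counts) {
  exon_counts <- as.matrix(exon_counts)
  if (ncol(exon_counts) < 2) stop("need at least 2 samples")
  if (!any(rowSums(exon_counts > 0) == ncol(exon_counts)))
    stop("no gene with nonzero counts in all samples")
  DESeq2::estimateSizeFactorsForMatrix(exon_counts)
}

#' Intron/exon coverage ratio per gene
#'
#' Mean intron coverage divided by mean exon coverage per gene, where mean
#' coverage is the size-factor-normalized read count divided by the total
#' feature length. Only high-expressed genes with mean combined
#' (exon + intron) counts per million above `cfg$cpm_min` are kept (the size
#' factors themselves remain exon-count based). Degenerate ratios are
#' substituted:
#' genes with no exon counts get `cfg$ratio_hi` (1); genes with (nearly) no
#' intron counts — zero raw intron counts, or a computed ratio below
#' `cfg$ratio_lo` — get `cfg$ratio_lo` (0.001). Genes with neither exon nor
#' intron counts are excluded with a message.
#'
#' @param exon_counts,intron_counts integer matrices, genes x samples, with
#'   identical row order (gene universe) and columns.
#' @param exon_lengths,intron_lengths named (or row-aligned) total feature
#'   lengths in bp; genes with `intron_lengths == 0` (intronless) are
#'   excluded.
#' @param sf size factors from [size_factors()] (exon-count based); computed
#'   when omitted.
#' @param cfg an [analysis_config].
#' @return data.frame `gene_id`, `mean_exon_coverage`,
#'   `mean_intron_coverage`, `ratio`, `flag`
#'   (`"none"`/`"no_exon"`/`"low_intron"`).
#' @export
intron_exon_ratio <- function(exon_counts, intron_counts, exon_lengths,
                              intron_lengths, sf = NULL,
                              cfg = analysis_config()) {
  exon_counts <- as.matrix(exon_counts); intron_counts <- as.matrix(intron_counts)
  stopifnot(nrow(exon_counts) == nrow(intron_counts),
            ncol(exon_counts) == ncol(intron_counts))
  gid <- rownames(exon_counts)
  if (is.null(gid)) stop("exon_counts needs gene ids as rownames")
  if (is.null(sf)) sf <- size_factors(exon_counts)
  ## CPM filter on combined raw counts: exon-only CPM would make the
  ## "no exon counts" substitution unreachable
  tot <- exon_counts + intron_counts
  cpm <- sweep(tot, 2, colSums(tot), "/") * 1e6
  keep <- rowMeans(cpm) > cfg$cpm_min & intron_lengths > 0
  both_zero <- rowSums(exon_counts) == 0 & rowSums(intron_counts) == 0
  if (any(keep & both_zero)) {
    message(sum(keep & both_zero), " gene(s) with zero exon and intron counts excluded")
    keep <- keep & !both_zero
  }
  ne <- sweep(exon_counts[keep, , drop = FALSE], 2, sf, "/")
  ni <- sweep(intron_counts[keep, , drop = FALSE], 2, sf, "/")
  mec <- rowMeans(ne) / exon_lengths[keep]
  mic <- rowMeans(ni) / intron_lengths[keep]
  ratio <- mic / mec
  flag <- rep("none", sum(keep))
  no_exon <- rowSums(exon_counts[keep, , drop = FALSE]) == 0
  ratio[no_exon] <- cfg$ratio_hi
  flag[no_exon] <- "no_exon"
  low_intr <- !no_exon &
    (rowSums(intron_counts[keep, , drop = FALSE]) == 0 | ratio < cfg$ratio_lo)
  ratio[low_intr] <- cfg$ratio_lo
  flag[low_intr] <- "low_intron"
  data.frame(gene_id = gid[keep], mean_exon_coverage = mec,
             mean_intron_coverage = mic, ratio = ratio, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate intron/exon ratio changes with expression changes
#'
#' Per gene, pairs the log2 fold-change in expression with the log2 change
#' in intron/exon ratio between two conditions (e.g. knock-down vs control),
#' and reports the Spearman rank correlation. A negative correlation
#' indicates increased intron retention in downregulated genes. Genes must
#' pass the CPM filter in both conditions (i.e. appear in both ratio
#' tables).
#'
#' @param ratio_ctrl,ratio_cond [intron_exon_ratio()] tables for the two
#'   conditions.
#' @param de DE table with `gene_id` and `log2FC`.
#' @return list with `table` (gene_id, log2FC, log2_ratio_change), `rho`,
#'   `p_value`, and `flagged` (`TRUE` when the correlation is undefined,
#'   e.g. all ratio changes zero).
#' @export
ratio_vs_fc <- function(ratio_ctrl, ratio_cond, de) {
  shared <- Reduce(intersect, list(ratio_ctrl$gene_id, ratio_cond$gene_id,
                                   de$gene_id))
  if (length(shared) < 10)
    warning("only ", length(shared), " genes shared between ratio tables and DE table")
  tab <- data.frame(
    gene_id = shared,
    log2FC = de$log2FC[match(shared, de$gene_id)],
    log2_ratio_change = log2(ratio_cond$ratio[match(shared, ratio_cond$gene_id)] /
                             ratio_ctrl$ratio[match(shared, ratio_ctrl$gene_id)]),
    stringsAsFactors = FALSE)
  if (nrow(tab) < 3 || stats::sd(tab$log2_ratio_change) == 0 ||
      stats::sd(tab$log2FC) == 0) {
    return(list(table = tab, rho = NA_real_, p_value = NA_real_, flagged = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(tab$log2FC, tab$log2_ratio_change, method = "spearman"))
  list(table = tab, rho = unname(ct$estimate), p_value = ct$p.value,
       flagged = FALSE)
}
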