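## mean per bin; a trailing partial bin is averaged over its actual width
.bin_mean <- function(v, bin) {
  if (bin == 1L) return(v)
  n <- length(v)
  nb <- ceiling(n / bin)
  grp <- rep(seq_len(nb), each = bin, length.out = n)
  as.numeric(tapply(v, grp, mean))
}

.metagene_matrix <- function(mat, layout, anchors) {
  rownames(mat) <- anchors
  attr(mat, "layout") <- layout
  class(mat) <- c("metagene_matrix", class(mat))
  mat
}

#' Scaled-region metagene matrix
#'
#' Per-gene signal vector over: `b` bp upstream flank, the first
#' `unscaled5` bp of the gene, the remaining gene body linearly rescaled to
#' `body` bp, the last `unscaled3` bp, and `a` bp downstream flank — all
#' averaged in `bin`-bp bins, oriented so the TSS is on the left for both
#' strands. Defaults (1000/1000/500/500/500 at 10 bp) give 350 columns.
#' Genes shorter than `unscaled5 + unscaled3 + 1` bp are dropped with a
#' message, as are genes on chromosomes absent from the track.
#'
#' Body rescaling is linear interpolation of the per-base body signal onto
#' `body` equally spaced points, so constant signal is preserved exactly.
#'
#' @param track a [coverage_track].
#' @param ann a [gene_annotation] or gene-level `GRanges`.
#' @param cfg an [analysis_config]; `cfg$metagene` sets the layout.
#' @param signal `"combined"`, `"plus"` or `"minus"` strand view of the track.
#' @return A numeric matrix (genes x bins) with a `layout` attribute giving
#'   the column index ranges of the five segments.
#' @export
metagene_scaled <- function(track, ann, cfg = analysis_config(),
                            signal = "combined") {
  genes <- if (inherits(ann, "gene_annotation")) ann$genes else ann
  ly <- cfg$metagene
  min_len <- ly$unscaled5 + ly$unscaled3 + 1L
  chrom <- as.character(GenomicRanges::seqnames(genes))
  known <- chrom %in% names(track$seqlengths)
  long <- GenomicRanges::width(genes) >= min_len
  drop <- !known | !long
  if (any(drop))
    message(sum(drop), " gene(s) dropped from scaled metagene (short or unknown chromosome)")
  genes <- genes[!drop]; chrom <- chrom[!drop]
  nbin <- (ly$b + ly$unscaled5 + ly$body + ly$unscaled3 + ly$a) %/% ly$bin
  mat <- matrix(0, nrow = length(genes), ncol = nbin)
  for (i in seq_along(genes)) {
    s <- GenomicRanges::start(genes)[i]; e <- GenomicRanges::end(genes)[i]
    minus <- as.character(GenomicRanges::strand(genes))[i] == "-"
    v <- .track_slice(track, chrom[i], s - ifelse(minus, ly$a, ly$b),
                      e + ifelse(minus, ly$b, ly$a), signal)
    if (minus) v <- rev(v)
    L <- e - s + 1L
    flank5 <- v[seq_len(ly$b)]
    un5 <- v[ly$b + seq_len(ly$unscaled5)]
    body <- v[ly$b + ly$unscaled5 + seq_len(L - ly$unscaled5 - ly$unscaled3)]
    un3 <- v[ly$b + (L - ly$unscaled3) + seq_len(ly$unscaled3)]
    flank3 <- v[ly$b + L + seq_len(ly$a)]
    body_scaled <- if (length(body) == ly$body) body
      else if (length(body) == 1L) rep(body, ly$body)
      else stats::approx(seq_along(body), body,
                         xout = seq(1, length(body), length.out = ly$body))$y
    mat[i, ] <- .bin_mean(c(flank5, un5, body_scaled, un3, flank3), ly$bin)
  }
  seg_bins <- c(flank5 = ly$b, unscaled5 = ly$unscaled5, body = ly$body,
                unscaled3 = ly$unscaled3, flank3 = ly$a) %/% ly$bin
  ends <- cumsum(seg_bins)
  layout <- list(mode = "scaled", bin = ly$bin, segments = Map(
    function(st, en) c(start = st, end = en),
    c(1, head(ends, -1) + 1), ends))
  names(layout$segments) <- names(seg_bins)
  .metagene_matrix(mat, layout, genes$gene_id)
}

#' Reference-point metagene matrix
#'
#' Signal in the window `b` bp before to `a` bp after each anchor (e.g. the
#' TSS), in transcription orientation (minus-strand rows are reversed so the
#' anchor always reads left to right), averaged in `bin`-bp bins. Windows
#' running off a chromosome are zero-padded.
#'
#' @param track a [coverage_track].
#' @param anchors width-1 stranded `GRanges` (e.g. [tss_anchors()]); a
#'   `gene_id` column is used for row names when present.
#' @param b,a window extent before/after the anchor in bp.
#' @param bin bin width in bp.
#' @param signal `"combined"`, `"sense"`, `"antisense"`, `"plus"` or
#'   `"minus"`: `sense`/`antisense` pick the anchor-strand (resp. opposite)
#'   signal per row.
#' @return A numeric matrix (anchors x bins) with a `layout` attribute.
#' @export
metagene_refpoint <- function(track, anchors, b = 500L, a = 500L, bin = 1L,
                              signal = c("combined", "sense", "antisense",
                                         "plus", "minus")) {
  signal <- match.arg(signal)
  stopifnot(is(anchors, "GRanges"))
  chrom <- as.character(GenomicRanges::seqnames(anchors))
  strand <- as.character(GenomicRanges::strand(anchors))
  pos <- GenomicRanges::start(anchors)
  mat <- matrix(0, nrow = length(anchors), ncol = length(.bin_mean(numeric(b + a), bin)))
  for (i in seq_along(anchors)) {
    minus <- strand[i] == "-"
    sig <- switch(signal,
      combined = "combined", plus = "plus", minus = "minus",
      sense = if (minus) "minus" else "plus",
      antisense = if (minus) "plus" else "minus")
    v <- if (!minus) {
      .track_slice(track, chrom[i], pos[i] - b, pos[i] + a - 1L, sig)
    } else {
      rev(.track_slice(track, chrom[i], pos[i] - a + 1L, pos[i] + b, sig))
    }
    mat[i, ] <- .bin_mean(v, bin)
  }
  ids <- if (!is.null(anchors$gene_id)) anchors$gene_id else as.character(seq_along(anchors))
  .metagene_matrix(mat, list(mode = "refpoint", b = b, a = a, bin = bin), ids)
}

#' Pol II travelling ratio (pausing index)
#'
#' Ratio of signal in the promoter-proximal window (`[TSS, TSS + w)` in
#' transcription orientation, `w = cfg$pausing_window`, default 250 bp) to
#' signal over the remaining transcribed region (`[TSS + w, TES]`). Genes
#' not longer than the window are excluded with a message; genes with zero
#' body signal are flagged (`TR = Inf`), not dropped.
#'
#' The ratio is invariant to global rescaling of the track, so raw or
#' per-million signal give identical values.
#'
#' @param track a [coverage_track] (e.g. extended Pol II ChIP fragments).
#' @param ann a [gene_annotation] or gene-level `GRanges`.
#' @param cfg an [analysis_config].
#' @param signal strand view passed to the track slice.
#' @return data.frame `gene_id`, `promoter_count`, `body_count`,
#'   `travelling_ratio`, `flagged`.
#' @export
pausing_index <- function(track, ann, cfg = analysis_config(),
                          signal = "combined") {
  genes <- if (inherits(ann, "gene_annotation")) ann$genes else ann
  w <- cfg$pausing_window
  short <- GenomicRanges::width(genes) <= w
  if (any(short))
    message(sum(short), " gene(s) shorter than the pausing window excluded")
  genes <- genes[!short]
  chrom <- as.character(GenomicRanges::seqnames(genes))
  strand <- as.character(GenomicRanges::strand(genes))
  s <- GenomicRanges::start(genes); e <- GenomicRanges::end(genes)
  prom <- body <- numeric(length(genes))
  for (i in seq_along(genes)) {
    v <- .track_slice(track, chrom[i], s[i], e[i], signal)
    if (strand[i] == "-") v <- rev(v)
    prom[i] <- sum(v[seq_len(w)])
    body[i] <- sum(v[(w + 1L):length(v)])
  }
  data.frame(gene_id = genes$gene_id, promoter_count = prom,
             body_count = body,
             travelling_ratio = ifelse(body > 0, prom / body, Inf),
             flagged = body == 0, stringsAsFactors = FALSE)
}

#' Normalize a Pol II metagene matrix on unchanged genes
#'
#' Removes library-specific ChIP-efficiency differences using a reference
#' set of high-expressed genes whose expression is unchanged between
#' conditions: first subtract the mean baseline signal over the gene body of
#' those genes (the scaled-body bins only, i.e. excluding the unscaled
#' TSS-/TES-proximal segments), then divide by the mean of the subtracted
#' signal over TSS ± 1 kb of the same genes. After normalization the
#' unchanged-gene TSS ± 1 kb mean is exactly 1, and the transformation is
#' invariant to affine (scale + offset) differences between libraries.
#'
#' @param mat a scaled metagene matrix from [metagene_scaled()].
#' @param unchanged_genes character vector of reference gene ids (must be
#'   rows of `mat`; at least 10).
#' @return The normalized matrix (same shape, `normalization` attribute set
#'   to `"unchanged-gene"`), with attributes `baseline` and `tss_scale`.
#' @export
normalize_polII <- function(mat, unchanged_genes) {
  ly <- attr(mat, "layout")
  if (is.null(ly) || ly$mode != "scaled")
    stop("mat must be a scaled metagene matrix")
  ref <- intersect(unchanged_genes, rownames(mat))
  if (length(ref) < 10) stop("need at least 10 unchanged reference genes in the matrix")
  seg <- ly$segments
  body_cols <- seg$body["start"]:seg$body["end"]
  ## TSS sits at the flank5/unscaled5 boundary; +/- 1 kb at the configured
  ## bin width covers the flank5 and unscaled5 segments (or is clipped to them)
  half <- 1000L %/% ly$bin
  tss_cols <- c(max(seg$flank5["start"], seg$flank5["end"] - half + 1L):seg$flank5["end"],
                seg$unscaled5["start"]:min(seg$unscaled5["end"],
                                           seg$unscaled5["start"] + half - 1L))
  beta <- mean(mat[ref, body_cols])
  mu <- mean(mat[ref, tss_cols] - beta)
  if (mu <= 0) stop("degenerate reference set: TSS-region mean <= 0 after baseline subtraction")
  out <- (mat - beta) / mu
  attr(out, "layout") <- ly
  attr(out, "normalization") <- "unchanged-gene"
  attr(out, "baseline") <- beta
  attr(out, "tss_scale") <- mu
  out
}

#' Select high-expressed unchanged genes
#'
#' Picks genes compatible with "no change" — point estimate
#' `|log2FC| < cfg$de_fc_min` and `padj > cfg$unchanged_padj_min` under the
#' standard test — ranked by mean expression, returning the top `n`. This is
#' the reference set used by [normalize_polII()] (199 genes in this
#' pipeline's study configuration).
#'
#' @param de DE table (`gene_id`, `mean_expression`, `log2FC`, `padj`).
#' @param n number of genes to return.
#' @param cfg an [analysis_config].
#' @return character vector of gene ids (fewer than `n` with a warning when
#'   not enough genes qualify). Ties in expression break by gene_id.
#' @export
select_unchanged_genes <- function(de, n = 199L, cfg = analysis_config()) {
  ok <- !is.na(de$log2FC) & !is.na(de$padj) &
    abs(de$log2FC) < cfg$de_fc_min & de$padj > cfg$unchanged_padj_min
  cand <- de[ok, , drop = FALSE]
  cand <- cand[order(-cand$mean_expression, cand$gene_id), , drop = FALSE]
  if (nrow(cand) < n) {
    warning("only ", nrow(cand), " genes qualify as unchanged (requested ", n, ")")
    n <- nrow(cand)
  }
  head(cand$gene_id, n)
}
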