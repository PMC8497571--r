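#' Nearest neighbour of a gene by direction and orientation
#'
#' Finds the nearest gene relative to a focal gene in one of four
#' direction/orientation categories, interpreted on the focal gene's strand:
#' `upstream`/`downstream` refer to the 5'/3' side of the focal gene, and
#' `sense`/`antisense` to same/opposite strand. The distance is the genomic
#' gap between the two gene spans (overlapping or abutting spans give 0;
#' overlapping genes qualify in both directions). Ties are broken by the
#' lexicographically smaller gene_id.
#'
#' @param gene_id focal gene id.
#' @param direction `"upstream"` or `"downstream"`.
#' @param orientation `"sense"` or `"antisense"`.
#' @param genes gene-level `GRanges` (the search universe) or a
#'   [gene_annotation].
#' @return list with `neighbour` (gene_id or `NA`) and `distance`
#'   (bp; `Inf` when no qualifying gene exists).
#' @export
find_neighbor <- function(gene_id, direction = c("upstream", "downstream"),
                          orientation = c("sense", "antisense"), genes) {
  direction <- match.arg(direction)
  orientation <- match.arg(orientation)
  genes <- if (inherits(genes, "gene_annotation")) genes$genes else genes
  i <- match(gene_id, genes$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  .neighbor_one(i, direction, orientation,
                chrom = as.character(GenomicRanges::seqnames(genes)),
                start = GenomicRanges::start(genes),
                end = GenomicRanges::end(genes),
                strand = as.character(GenomicRanges::strand(genes)),
                ids = genes$gene_id)
}

## core single-gene search over parallel vectors
.neighbor_one <- function(i, direction, orientation, chrom, start, end,
                          strand, ids) {
  same_chr <- chrom == chrom[i]
  same_chr[i] <- FALSE
  want_strand <- if (orientation == "sense") strand[i] else
    setdiff(c("+", "-"), strand[i])
  cand <- which(same_chr & strand == want_strand)
  if (!length(cand)) return(list(neighbour = NA_character_, distance = Inf))
  ## genomic side of the focal gene corresponding to `direction`
  left_is_upstream <- strand[i] == "+"
  gap_left  <- start[i] - end[cand] - 1L   # >= 0 when candidate fully left
  gap_right <- start[cand] - end[i] - 1L   # >= 0 when candidate fully right
  overlaps <- gap_left < 0L & gap_right < 0L
  on_side <- if ((direction == "upstream") == left_is_upstream) {
    gap_left >= 0L
  } else {
    gap_right >= 0L
  }
  dist <- ifelse(overlaps, 0L, pmax(gap_left, gap_right))
  ok <- on_side | overlaps
  if (!any(ok)) return(list(neighbour = NA_character_, distance = Inf))
  cand <- cand[ok]; dist <- dist[ok]
  d <- min(dist)
  hits <- cand[dist == d]
  list(neighbour = ids[hits][order(ids[hits])][1], distance = as.numeric(d))
}

#' Annotate all genes with their four nearest neighbours
#'
#' Runs [find_neighbor()] for every gene and every
#' direction/orientation category and flags neighbours closer than
#' `cfg$pair_max_dist` (strict inequality; head-to-head pairs closer than
#' 1 kb are the divergent gene pairs of interest).
#'
#' @param ann a [gene_annotation] or gene-level `GRanges`.
#' @param cfg an [analysis_config]; `pair_max_dist` sets the threshold.
#' @return data.frame with one row per gene; for each category
#'   `upstream_antisense`, `upstream_sense`, `downstream_antisense`,
#'   `downstream_sense` the columns `<cat>_id`, `<cat>_dist` and
#'   `<cat>_within`.
#' @export
annotate_pairs <- function(ann, cfg = analysis_config()) {
  genes <- if (inherits(ann, "gene_annotation")) ann$genes else ann
  n <- length(genes)
  chrom <- as.character(GenomicRanges::seqnames(genes))
  start <- GenomicRanges::start(genes)
  end <- GenomicRanges::end(genes)
  strand <- as.character(GenomicRanges::strand(genes))
  ids <- genes$gene_id
  cats <- expand.grid(direction = c("upstream", "downstream"),
                      orientation = c("antisense", "sense"),
                      stringsAsFactors = FALSE)
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  by_chrom <- split(seq_len(n), chrom)
  for (k in seq_len(nrow(cats))) {
    dir <- cats$direction[k]; ori <- cats$orientation[k]
    nb <- character(n); dist <- numeric(n)
    for (idx in by_chrom) {
      ## search within one chromosome only (the candidates are local)
      for (j in seq_along(idx)) {
        r <- .neighbor_one(j, dir, ori, chrom[idx], start[idx], end[idx],
                           strand[idx], ids[idx])
        nb[idx[j]] <- r$neighbour; dist[idx[j]] <- r$distance
      }
    }
    cat_nm <- paste(dir, ori, sep = "_")
    out[[paste0(cat_nm, "_id")]] <- nb
    out[[paste0(cat_nm, "_dist")]] <- dist
    out[[paste0(cat_nm, "_within")]] <- !is.na(nb) & dist < cfg$pair_max_dist
  }
  out
}

#' Pair-category frequencies for a gene set
#'
#' Fraction of genes (optionally restricted to `gene_set`) with a neighbour
#' within the distance threshold, per category — the quantity compared
#' between DE classes and all genes.
#'
#' @param pairs output of [annotate_pairs()].
#' @param gene_set optional character vector of gene ids.
#' @return named numeric vector of fractions (one per category).
#' @export
pair_frequencies <- function(pairs, gene_set = NULL) {
  if (!is.null(gene_set)) pairs <- pairs[pairs$gene_id %in% gene_set, , drop = FALSE]
  if (!nrow(pairs)) stop("empty gene set")
  cols <- grep("_within$", names(pairs), value = TRUE)
  out <- vapply(pairs[cols], mean, numeric(1))
  names(out) <- sub("_within$", "", cols)
  out
}

#' Call bidirectional promoters from opposite-strand TSS signal
#'
#' Flags each gene whose TSS shows initiation signal on the opposite strand
#' within `cfg$antisense_window` nucleotides upstream of the TSS (the region
#' a divergent transcript initiates into). Evidence is either a stranded
#' peak set (e.g. CAGE peaks) overlapping the window on the opposite strand,
#' or summed opposite-strand coverage above `min_signal`. With
#' `window = "centered"` the window is instead centred on the TSS
#' (± `antisense_window`), for sensitivity analysis.
#'
#' @param ann a [gene_annotation] or gene-level `GRanges`.
#' @param signal stranded `GRanges` of peaks, or a [coverage_track].
#' @param cfg an [analysis_config].
#' @param window `"upstream"` (default) or `"centered"`.
#' @param min_signal coverage-sum threshold when `signal` is a track.
#' @return data.frame `gene_id`, `bidirectional`, `evidence`
#'   (`"cage_peak"`/`"read_count"`), `window_bp`.
#' @export
call_bidirectional <- function(ann, signal, cfg = analysis_config(),
                               window = c("upstream", "centered"),
                               min_signal = 0) {
  window <- match.arg(window)
  genes <- if (inherits(ann, "gene_annotation")) ann$genes else ann
  w <- cfg$antisense_window
  tss <- tss_anchors(genes)
  ## window on the opposite strand, upstream of (or centred on) the TSS
  win <- if (window == "upstream") {
    GenomicRanges::flank(tss, width = w, start = TRUE)   # strand-aware 5' flank
  } else {
    GenomicRanges::resize(tss, width = 2L * w + 1L, fix = "center")
  }
  GenomicRanges::start(win) <- pmax(GenomicRanges::start(win), 1L)
  opp <- ifelse(as.character(GenomicRanges::strand(genes)) == "+", "-", "+")
  if (is(signal, "GRanges")) {
    sstr <- as.character(GenomicRanges::strand(signal))
    if (any(sstr == "*")) stop("signal must be stranded")
    hit <- GenomicRanges::findOverlaps(win, signal, ignore.strand = TRUE)
    has <- logical(length(genes))
    ok <- sstr[S4Vectors::subjectHits(hit)] == opp[S4Vectors::queryHits(hit)]
    has[unique(S4Vectors::queryHits(hit)[ok])] <- TRUE
    evidence <- "cage_peak"
  } else if (inherits(signal, "coverage_track")) {
    if (signal$strand_mode != "stranded") stop("signal must be stranded")
    has <- vapply(seq_along(genes), function(i) {
      rle <- if (opp[i] == "+") signal$plus else signal$minus
      sum(.signal_slice(rle, as.character(GenomicRanges::seqnames(win))[i],
                        GenomicRanges::start(win)[i],
                        GenomicRanges::end(win)[i])) > min_signal
    }, logical(1))
    evidence <- "read_count"
  } else stop("signal must be a stranded GRanges or a coverage_track")
  data.frame(gene_id = genes$gene_id, bidirectional = has,
             evidence = ifelse(has, evidence, NA_character_),
             window_bp = w, stringsAsFactors = FALSE)
}

#' Co-regulation of divergent gene pairs
#'
#' For focal genes of one DE class and their paired partner genes, relates
#' the partner's log2 fold-change to the focal gene's, stratified by partner
#' mean expression above/below `expression_floor` (co-regulation at
#' bidirectional promoters is expected mainly for highly expressed
#' partners). Reports the OLS slope of partner ~ focal and the two-sided
#' t-test of slope = 0 per stratum.
#'
#' @param pairs data.frame with columns `gene_id` (focal) and `partner_id`.
#' @param de_focal,de_partner DE tables ([classify_de()] input/output style:
#'   `gene_id`, `mean_expression`, `log2FC`).
#' @param expression_floor partner mean-expression threshold (same units as
#'   `mean_expression`, e.g. mean reads; pairs at or below go to the low
#'   stratum).
#' @return list with `pairs` (per-pair table with stratum) and `fits`, a
#'   data.frame per stratum: `stratum`, `n`, `slope`, `p_value` (`NA` and
#'   `flagged = TRUE` for strata with < 3 pairs).
#' @export
pair_coregulation <- function(pairs, de_focal, de_partner, expression_floor) {
  stopifnot(all(c("gene_id", "partner_id") %in% names(pairs)))
  m <- data.frame(
    gene_id = pairs$gene_id, partner_id = pairs$partner_id,
    stringsAsFactors = FALSE)
  m <- m[!is.na(m$partner_id), , drop = FALSE]
  m$fc_focal <- de_focal$log2FC[match(m$gene_id, de_focal$gene_id)]
  m$fc_partner <- de_partner$log2FC[match(m$partner_id, de_partner$gene_id)]
  m$partner_expr <- de_partner$mean_expression[match(m$partner_id, de_partner$gene_id)]
  m <- m[stats::complete.cases(m[c("fc_focal", "fc_partner", "partner_expr")]), ,
         drop = FALSE]
  m$stratum <- ifelse(m$partner_expr > expression_floor, "high", "low")
  fit_one <- function(d) {
    if (nrow(d) < 3)
      return(data.frame(n = nrow(d), slope = NA_real_, p_value = NA_real_,
                        flagged = TRUE))
    f <- stats::lm(fc_partner ~ fc_focal, data = d)
    co <- summary(f)$coefficients
    data.frame(n = nrow(d), slope = co["fc_focal", "Estimate"],
               p_value = co["fc_focal", "Pr(>|t|)"], flagged = FALSE)
  }
  fits <- do.call(rbind, lapply(c("high", "low"), function(s)
    cbind(stratum = s, fit_one(m[m$stratum == s, , drop = FALSE]))))
  list(pairs = m, fits = fits)
}
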