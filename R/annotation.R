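#' Gene annotation container
#'
#' Bundles gene-level and exon-level intervals for one annotation set.
#' `genes` is a [GenomicRanges::GRanges] with one range per gene (metadata
#' columns `gene_id`, `gene_name`, `biotype`); `exons` has one range per
#' exon annotation (an exon listed in k transcripts appears k times) with
#' metadata columns `gene_id` and `transcript_id`. Coordinates are 1-based
#' closed throughout.
#'
#' @param genes gene-level `GRanges`.
#' @param exons exon-level `GRanges` with `gene_id` and `transcript_id`.
#' @return An object of class `"gene_annotation"`.
#' @export
gene_annotation <- function(genes, exons) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRanges"))
  need_g <- c("gene_id", "gene_name", "biotype")
  for (nm in setdiff(need_g, names(S4Vectors::mcols(genes)))) {
    S4Vectors::mcols(genes)[[nm]] <- NA_character_
  }
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(c("gene_id", "transcript_id") %in% names(S4Vectors::mcols(exons))))
    stop("exons need gene_id and transcript_id metadata columns")
  if (!all(as.character(GenomicRanges::strand(genes)) %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  ## deterministic ordering: (chrom, start, gene_id)
  og <- order(as.character(GenomicRanges::seqnames(genes)),
              GenomicRanges::start(genes), genes$gene_id)
  genes <- genes[og]
  oe <- order(match(exons$gene_id, genes$gene_id), exons$transcript_id,
              GenomicRanges::start(exons))
  exons <- exons[oe]
  ## every exon must fall inside its gene's span
  idx <- match(exons$gene_id, genes$gene_id)
  if (anyNA(idx))
    stop("exon with unknown gene_id: ",
         paste(unique(exons$gene_id[is.na(idx)]), collapse = ", "))
  inside <- as.character(GenomicRanges::seqnames(exons)) ==
              as.character(GenomicRanges::seqnames(genes))[idx] &
            GenomicRanges::start(exons) >= GenomicRanges::start(genes)[idx] &
            GenomicRanges::end(exons) <= GenomicRanges::end(genes)[idx]
  if (!all(inside))
    stop("validation error: ", sum(!inside),
         " exon(s) outside the span of their gene (first: ",
         exons$gene_id[which(!inside)[1]], ")")
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exon annotations on %d chromosome(s)\n",
              length(x$genes), length(x$exons),
              length(unique(as.character(GenomicRanges::seqnames(x$genes))))))
  invisible(x)
}

## light line-level sanity scan so malformed input fails with a line number
.scan_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("GTF parse error at line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))))
      stop("GTF parse error at line ", i, ": non-numeric start/end")
  }
  invisible(TRUE)
}

#' Read a Gencode-style GTF into a gene annotation
#'
#' Parses a GTF file (Gencode attribute dialect: `gene_id`, `transcript_id`,
#' `gene_type`/`gene_biotype`, `gene_name`) with rtracklayer and returns the
#' genes of the requested biotype together with all their exon annotations.
#' GTF 1-based inclusive coordinates are kept as-is in the returned 1-based
#' closed `GRanges`. Genes are ordered deterministically by
#' (chromosome, start, gene_id).
#'
#' @param path GTF file path.
#' @param biotype biotype filter, e.g. `"protein_coding"`; `NULL` keeps all.
#' @return A [gene_annotation] object.
#' @export
read_gene_annotation <- function(path, biotype = "protein_coding") {
  if (!file.exists(path)) stop("no such file: ", path)
  .scan_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  bt <- if ("gene_type" %in% names(mc)) mc$gene_type
        else if ("gene_biotype" %in% names(mc)) mc$gene_biotype
        else rep(NA_character_, length(gr))
  if (!is.null(biotype)) {
    keep_gene <- unique(gr$gene_id[!is.na(bt) & bt == biotype])
    gr <- gr[gr$gene_id %in% keep_gene]
    mc <- S4Vectors::mcols(gr)
    bt <- if ("gene_type" %in% names(mc)) mc$gene_type else mc$gene_biotype
  }
  is_gene <- mc$type == "gene"
  is_exon <- mc$type == "exon"
  if (!any(is_exon)) stop("GTF contains no exon records")
  exons <- gr[is_exon]
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
    gene_id = exons$gene_id, transcript_id = exons$transcript_id)
  if (any(is_gene)) {
    genes <- gr[is_gene]
    gname <- if ("gene_name" %in% names(S4Vectors::mcols(genes)))
               genes$gene_name else genes$gene_id
    gbt <- bt[is_gene]
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = genes$gene_id, gene_name = gname, biotype = gbt)
  } else {
    ## no explicit gene records: derive gene spans from exon extents
    sp <- GenomicRanges::split(exons, exons$gene_id)
    rg <- unlist(range(sp))
    genes <- rg
    genes$gene_id <- names(rg)
    genes$gene_name <- names(rg)
    genes$biotype <- bt[match(names(rg), gr$gene_id)]
    names(genes) <- NULL
  }
  gene_annotation(genes, exons)
}

#' Gene-level TSS anchors
#'
#' The gene-level TSS is the 5'-most position of the gene span on the gene's
#' strand (start for `+`, end for `-` genes). Returns width-1 anchors that
#' keep the gene strand, suitable for reference-point metagenes and
#' bidirectionality calls.
#'
#' @param ann a [gene_annotation], or a gene-level `GRanges`.
#' @return `GRanges` of width-1 TSS anchors with a `gene_id` column.
#' @export
tss_anchors <- function(ann) {
  genes <- if (inherits(ann, "gene_annotation")) ann$genes else ann
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

## per-transcript TSS anchors (5'-most exon base of each transcript)
transcript_tss <- function(ann) {
  ex <- ann$exons
  sp <- GenomicRanges::split(ex, ex$transcript_id)
  rg <- unlist(range(sp))
  out <- GenomicRanges::resize(rg, width = 1L, fix = "start")
  out$transcript_id <- names(out)
  gid <- ex$gene_id[match(out$transcript_id, ex$transcript_id)]
  out$gene_id <- gid
  names(out) <- NULL
  out
}

#' Classify exons by transcript position
#'
#' Labels every exon annotation as first, internal and/or last within each
#' transcript (transcription orientation), then aggregates labels per unique
#' exon coordinate within each gene: an exon shared between transcripts
#' carries the union of its positional labels. `exclusively_first` marks
#' exons whose label set is exactly `{first}` across all transcripts of the
#' gene. A single-exon transcript contributes both `first` and `last`.
#'
#' @param ann a [gene_annotation].
#' @return A data.frame with one row per unique (gene, exon coordinate):
#'   columns `gene_id`, `chrom`, `start`, `end`, `strand`, `first`,
#'   `internal`, `last`, `exclusively_first`. Attributes
#'   `n_exon_annotations` (size of the exon multiset across transcripts) and
#'   `n_exclusively_first` carry the two summary counts.
#' @export
classify_exons <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  ex <- ann$exons
  df <- data.frame(
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE)
  ## position within transcript, in transcription orientation
  sp <- split(seq_len(nrow(df)), df$transcript_id)
  first <- internal <- last <- logical(nrow(df))
  for (idx in sp) {
    o <- order(df$start[idx])
    if (df$strand[idx[1]] == "-") o <- rev(o)
    idx <- idx[o]
    n <- length(idx)
    first[idx[1]] <- TRUE
    last[idx[n]] <- TRUE
    if (n > 2) internal[idx[2:(n - 1)]] <- TRUE
  }
  df$first <- first; df$internal <- internal; df$last <- last
  key <- paste(df$gene_id, df$chrom, df$start, df$end, df$strand, sep = "\r")
  agg <- data.frame(
    key = unique(key), stringsAsFactors = FALSE)
  m <- match(key, agg$key)
  agg$first    <- as.logical(tapply(df$first, m, any))
  agg$internal <- as.logical(tapply(df$internal, m, any))
  agg$last     <- as.logical(tapply(df$last, m, any))
  firstrow <- match(agg$key, key)
  out <- data.frame(
    gene_id = df$gene_id[firstrow],
    chrom = df$chrom[firstrow],
    start = df$start[firstrow],
    end = df$end[firstrow],
    strand = df$strand[firstrow],
    first = agg$first, internal = agg$internal, last = agg$last,
    stringsAsFactors = FALSE)
  out$exclusively_first <- out$first & !out$internal & !out$last
  out <- out[order(out$gene_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_exon_annotations") <- nrow(df)
  attr(out, "n_exclusively_first") <- sum(out$exclusively_first)
  out
}

#' Derive introns by subtracting exons from the gene span
#'
#' Introns are the gene span minus the union of all exons of all transcripts
#' of the gene, returned as maximal disjoint intervals in genomic order.
#'
#' @param ann a [gene_annotation].
#' @param gene_ids optional character vector restricting to some genes.
#' @return `GRanges` of introns with a `gene_id` metadata column (empty for
#'   genes fully covered by exons).
#' @export
derive_introns <- function(ann, gene_ids = NULL) {
  stopifnot(inherits(ann, "gene_annotation"))
  genes <- ann$genes
  if (!is.null(gene_ids)) genes <- genes[genes$gene_id %in% gene_ids]
  ex <- ann$exons[ann$exons$gene_id %in% genes$gene_id]
  exl <- GenomicRanges::reduce(GenomicRanges::split(
    GenomicRanges::granges(ex), factor(ex$gene_id, levels = genes$gene_id)))
  intl <- GenomicRanges::psetdiff(GenomicRanges::granges(genes), exl)
  out <- unlist(intl, use.names = FALSE)
  if (length(out))
    out$gene_id <- rep(genes$gene_id, S4Vectors::elementNROWS(intl))
  out
}

#' Promoter windows around transcript start sites
#'
#' One strand-aware window per transcript TSS, spanning
#' `promoter_window["upstream"]` bp upstream to
#' `promoter_window["downstream"]` bp downstream of the TSS (default
#' -900/+100). Windows extending past the chromosome start are clipped at
#' position 1.
#'
#' @param ann a [gene_annotation] (per-transcript windows) or a `GRanges` of
#'   TSS anchors.
#' @param cfg an [analysis_config].
#' @return `GRanges` of promoter windows.
#' @export
promoter_windows <- function(ann, cfg = analysis_config()) {
  anchors <- if (inherits(ann, "gene_annotation")) transcript_tss(ann) else ann
  up <- cfg$promoter_window[["upstream"]]
  dn <- cfg$promoter_window[["downstream"]]
  pr <- GenomicRanges::promoters(anchors, upstream = up, downstream = dn)
  ## clip at chromosome start (and end where seqlengths are known)
  GenomicRanges::start(pr) <- pmax(GenomicRanges::start(pr), 1L)
  pr <- GenomicRanges::trim(pr)
  pr
}

#' Define enhancers as peaks not overlapping any promoter
#'
#' Keeps peaks (e.g. merged H3K4me1 peaks) with zero overlap against any
#' promoter window — a single shared base pair excludes the peak. Peak
#' centres are attached for reference-point profiling (±3 kb).
#'
#' @param peaks `GRanges` of peaks (strand ignored).
#' @param promoters `GRanges` of promoter windows, e.g. [promoter_windows()].
#' @return `GRanges` of enhancer peaks with a `center` metadata column.
#' @export
define_enhancers <- function(peaks, promoters) {
  stopifnot(is(peaks, "GRanges"), is(promoters, "GRanges"))
  if (length(promoters)) {
    hit <- IRanges::overlapsAny(peaks, promoters, ignore.strand = TRUE)
    out <- peaks[!hit]
  } else {
    out <- peaks
  }
  out$center <- GenomicRanges::start(out) +
    (GenomicRanges::width(out) - 1L) %/% 2L
  out
}

#' Merge interval sets across replicates
#'
#' Unions any number of interval sets and coalesces overlapping or abutting
#' intervals, as done when merging replicate peak calls.
#'
#' @param ... `GRanges` objects (or a single list of them).
#' @return A single merged `GRanges` (strand ignored).
#' @export
merge_intervals <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "GRanges"))
    sets <- sets[[1]]
  if (!length(sets)) stop("need at least one interval set")
  all <- suppressWarnings(do.call(c, lapply(sets, GenomicRanges::granges)))
  GenomicRanges::reduce(all, ignore.strand = TRUE)
}
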