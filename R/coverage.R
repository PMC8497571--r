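#' Strand-resolved coverage track
#'
#' Container for per-base signal over a genome, split by strand. `plus` and
#' `minus` are [IRanges::RleList] objects over the same chromosomes; for
#' unstranded data all signal lives in `plus`. Constructed by
#' [fragments_to_coverage()] or [read_bedgraph_pair()].
#'
#' @param plus,minus per-chromosome `RleList` signal.
#' @param seqlengths named integer chromosome lengths.
#' @param strand_mode `"stranded"` or `"unstranded"`.
#' @param normalization free-text tag (`"raw"`, `"per-million"`, `"custom"`).
#' @return An object of class `"coverage_track"`.
#' @export
coverage_track <- function(plus, minus = NULL, seqlengths,
                           strand_mode = c("stranded", "unstranded"),
                           normalization = "raw") {
  strand_mode <- match.arg(strand_mode)
  if (is.null(minus)) {
    minus <- IRanges::RleList(lapply(seqlengths, function(L)
      S4Vectors::Rle(0, L)))
    names(minus) <- names(seqlengths)
  }
  if (any(vapply(plus, function(r) any(S4Vectors::runValue(r) < 0), logical(1))) ||
      any(vapply(minus, function(r) any(S4Vectors::runValue(r) < 0), logical(1))))
    stop("coverage signal must be non-negative")
  structure(list(plus = plus, minus = minus,
                 seqlengths = seqlengths, strand_mode = strand_mode,
                 normalization = normalization),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track (%s, %s): %d chromosome(s), total signal %.4g (+) / %.4g (-)\n",
              x$strand_mode, x$normalization, length(x$seqlengths),
              sum(vapply(x$plus, function(r) sum(as.numeric(r)), numeric(1))),
              sum(vapply(x$minus, function(r) sum(as.numeric(r)), numeric(1)))))
  invisible(x)
}

## dense numeric slice [start, end] of an RleList, zero-padded outside the
## chromosome (and for chromosomes absent from the track)
.signal_slice <- function(rlelist, chrom, start, end) {
  n <- end - start + 1L
  if (!(chrom %in% names(rlelist))) return(numeric(n))
  r <- rlelist[[chrom]]
  L <- length(r)
  lo <- max(start, 1L); hi <- min(end, L)
  if (lo > hi) return(numeric(n))
  v <- as.numeric(S4Vectors::window(r, lo, hi))
  c(numeric(lo - start), v, numeric(end - hi))
}

## combined (+ plus -) slice honouring the requested strand view
.track_slice <- function(track, chrom, start, end,
                         signal = c("combined", "plus", "minus")) {
  signal <- match.arg(signal)
  switch(signal,
    combined = .signal_slice(track$plus, chrom, start, end) +
               .signal_slice(track$minus, chrom, start, end),
    plus = .signal_slice(track$plus, chrom, start, end),
    minus = .signal_slice(track$minus, chrom, start, end))
}

#' Compute coverage from aligned fragments
#'
#' Turns fragment intervals (BED-style alignments imported as `GRanges`)
#' into per-base occupancy. Single-end ChIP fragments can be extended to
#' `extend` nt from their 5' end before stacking, matching the usual
#' fixed-fragment-size treatment (150 nt in this pipeline's configuration).
#' Fragments running past a chromosome end are clipped with a warning.
#'
#' @param fragments `GRanges` of fragments; strand used when
#'   `strand_mode = "stranded"`.
#' @param seqlengths named integer chromosome lengths; taken from
#'   `fragments` seqinfo when omitted.
#' @param extend extension length in nt, or `NULL` to keep fragment widths.
#' @param strand_mode `"stranded"` splits signal by fragment strand,
#'   `"unstranded"` pools it.
#' @param normalize if `TRUE`, scale to signal per million fragments.
#' @return A [coverage_track].
#' @export
fragments_to_coverage <- function(fragments, seqlengths = NULL, extend = NULL,
                                  strand_mode = c("stranded", "unstranded"),
                                  normalize = FALSE) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is(fragments, "GRanges"))
  if (is.null(seqlengths)) {
    seqlengths <- GenomeInfoDb::seqlengths(fragments)
    if (anyNA(seqlengths))
      stop("seqlengths must be supplied or present in the fragments' seqinfo")
  }
  fragments <- GenomeInfoDb::keepSeqlevels(
    fragments, names(seqlengths), pruning.mode = "coarse")
  GenomeInfoDb::seqlengths(fragments) <- seqlengths
  if (!is.null(extend))
    fragments <- suppressWarnings(
      GenomicRanges::resize(fragments, width = extend, fix = "start"))
  oob <- GenomicRanges::end(fragments) >
           seqlengths[as.character(GenomicRanges::seqnames(fragments))] |
         GenomicRanges::start(fragments) < 1L
  if (any(oob)) {
    warning(sum(oob), " fragment(s) clipped at chromosome boundaries")
    fragments <- GenomicRanges::trim(fragments)
  }
  nfrag <- length(fragments)
  cov_of <- function(gr) GenomicRanges::coverage(gr, width = seqlengths)
  if (strand_mode == "stranded") {
    str <- as.character(GenomicRanges::strand(fragments))
    plus <- cov_of(fragments[str != "-"])
    minus <- cov_of(fragments[str == "-"])
  } else {
    plus <- cov_of(fragments)
    minus <- NULL
  }
  tag <- "raw"
  if (normalize && nfrag > 0) {
    sc <- 1e6 / nfrag
    plus <- plus * sc
    if (!is.null(minus)) minus <- minus * sc
    tag <- "per-million"
  }
  coverage_track(plus, minus, seqlengths, strand_mode, tag)
}

#' Read a stranded bedGraph pair into a coverage track
#'
#' @param plus_path,minus_path bedGraph files with forward/reverse strand
#'   signal.
#' @param seqlengths named integer chromosome lengths.
#' @return A [coverage_track] (normalization tag `"raw"`).
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, seqlengths) {
  read_one <- function(p) {
    gr <- rtracklayer::import(p, format = "bedGraph")
    gr <- GenomeInfoDb::keepSeqlevels(gr, names(seqlengths)[names(seqlengths) %in%
                                        GenomeInfoDb::seqlevels(gr)],
                                      pruning.mode = "coarse")
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    GenomicRanges::coverage(gr, weight = gr$score, width = seqlengths)
  }
  coverage_track(read_one(plus_path), read_one(minus_path), seqlengths,
                 "stranded", "raw")
}

#' Write a coverage track as a stranded bedGraph pair
#'
#' @param track a [coverage_track].
#' @param plus_path,minus_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_bedgraph_pair <- function(track, plus_path, minus_path) {
  wr <- function(rlelist, path) {
    gr <- methods::as(rlelist, "GRanges")
    gr <- gr[gr$score != 0]
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  wr(track$plus, plus_path)
  wr(track$minus, minus_path)
  invisible(c(plus_path, minus_path))
}
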