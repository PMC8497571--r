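#' Analysis configuration
#'
#' Collects every numeric window and threshold used by the downstream
#' analyses in one validated list, so that each operation documents which
#' constant it consumes. Defaults correspond to the study conditions this
#' pipeline implements:
#'
#' * `pausing_window` (250 bp): promoter-proximal window of the travelling
#'   ratio, measured from the TSS in transcription orientation.
#' * `pair_max_dist` (1000 bp): maximal gap for a gene pair to count as
#'   "in close proximity".
#' * `antisense_window` (100 nt): window upstream of the TSS, on the
#'   opposite strand, screened for divergent initiation signal.
#' * `promoter_window` (-900/+100 bp around the TSS): promoter definition
#'   used to exclude promoter-overlapping peaks when defining enhancers.
#' * `read_extension` (150 nt): 3' extension applied to single-end ChIP
#'   fragments before coverage computation.
#' * `metagene`: scaled-region layout — flank `b` = 1000 bp, unscaled 5'
#'   segment 1000 bp, gene body scaled to `body` = 500 bp, unscaled 3'
#'   segment 500 bp, flank `a` = 500 bp, at `bin` = 10 bp resolution.
#' * `refpoint_tss` / `refpoint_atac`: reference-point layouts (±500 bp at
#'   1 bp bins; ±3000 bp).
#' * `de_fc_min` (0.3), `de_padj_max` (0.05): differential-expression class
#'   thresholds (strict inequalities).
#' * `cpm_min` (20): mean counts-per-million floor for the intron/exon ratio.
#' * `ratio_hi` (1), `ratio_lo` (0.001): substitutes for degenerate
#'   intron/exon ratios (no exon signal, resp. (nearly) no intron signal).
#' * `n_resample` (10000), `ci_level` (0.999): resampling null band.
#'
#' @param ... named overrides of any default listed above.
#' @return A list of class `"bipair_config"`.
#' @examples
#' cfg <- analysis_config(pair_max_dist = 500)
#' cfg$pair_max_dist
#' @export
analysis_config <- function(...) {
  cfg <- list(
    pausing_window   = 250L,
    pair_max_dist    = 1000L,
    antisense_window = 100L,
    promoter_window  = c(upstream = 900L, downstream = 100L),
    read_extension   = 150L,
    metagene         = list(b = 1000L, unscaled5 = 1000L, body = 500L,
                            unscaled3 = 500L, a = 500L, bin = 10L),
    refpoint_tss     = list(b = 500L, a = 500L, bin = 1L),
    refpoint_atac    = list(b = 3000L, a = 3000L, bin = 10L),
    de_fc_min        = 0.3,
    de_padj_max      = 0.05,
    unchanged_padj_min = 0.5,
    cpm_min          = 20,
    ratio_hi         = 1,
    ratio_lo         = 0.001,
    n_resample       = 10000L,
    ci_level         = 0.999,
    rng_seed         = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
        cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
      } else {
        cfg[[nm]] <- dots[[nm]]
      }
    }
  }
  stopifnot(
    cfg$pausing_window > 0, cfg$pair_max_dist >= 0, cfg$antisense_window > 0,
    all(cfg$promoter_window >= 0), cfg$read_extension >= 0,
    cfg$ci_level > 0, cfg$ci_level < 1, cfg$n_resample >= 1,
    cfg$metagene$bin > 0, cfg$ratio_lo > 0
  )
  class(cfg) <- "bipair_config"
  cfg
}

#' @export
print.bipair_config <- function(x, ...) {
  cat("bipair analysis configuration\n")
  flat <- x[!vapply(x, is.list, logical(1))]
  for (nm in names(flat)) {
    cat(sprintf("  %-18s %s\n", nm, paste(flat[[nm]], collapse = "/")))
  }
  cat(sprintf("  metagene           b=%d unscaled5=%d body=%d unscaled3=%d a=%d bin=%d\n",
              x$metagene$b, x$metagene$unscaled5, x$metagene$body,
              x$metagene$unscaled3, x$metagene$a, x$metagene$bin))
  invisible(x)
}
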