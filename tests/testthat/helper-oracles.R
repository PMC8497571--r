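## Fixture builders and independent brute-force oracles shared by the suite.
## Oracles deliberately use naive per-base / all-pairs code paths, never the
## package's own interval arithmetic.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

make_genes <- function(df) {
  GRanges(df$chrom, IRanges(df$start, df$end), df$strand,
          gene_id = df$gene_id, gene_name = df$gene_id,
          biotype = "protein_coding")
}

## random gene universe as a plain data.frame (overlaps allowed on purpose)
random_universe <- function(n_per_chrom, n_chrom, seed, span = 200000L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    start <- sort(sample.int(span, n_per_chrom))
    width <- sample(500:5000, n_per_chrom, replace = TRUE)
    data.frame(gene_id = sprintf("C%dG%03d", ch, seq_len(n_per_chrom)),
               chrom = paste0("chr", ch), start = start,
               end = start + width - 1L,
               strand = sample(c("+", "-"), n_per_chrom, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
}

## all-pairs nearest-neighbour oracle over a plain data.frame
oracle_neighbor <- function(df, i, direction, orientation) {
  want <- if (orientation == "sense") df$strand[i] else
    setdiff(c("+", "-"), df$strand[i])
  best_id <- NA_character_; best_d <- Inf
  for (j in seq_len(nrow(df))) {
    if (j == i || df$chrom[j] != df$chrom[i] || df$strand[j] != want) next
    if (df$end[j] < df$start[i]) {
      side <- "left"; d <- df$start[i] - df$end[j] - 1L
    } else if (df$start[j] > df$end[i]) {
      side <- "right"; d <- df$start[j] - df$end[i] - 1L
    } else {
      side <- "both"; d <- 0L
    }
    up_side <- if (df$strand[i] == "+") "left" else "right"
    ok <- side == "both" ||
      (direction == "upstream" && side == up_side) ||
      (direction == "downstream" && side != up_side)
    if (!ok) next
    if (d < best_d || (d == best_d && df$gene_id[j] < best_id)) {
      best_d <- d; best_id <- df$gene_id[j]
    }
  }
  list(neighbour = best_id, distance = as.numeric(best_d))
}

## two-sided Fisher p by direct hypergeometric enumeration (standard
## "sum of all tables no more probable than the observed" definition)
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  support <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= d[support == x_obs] * (1 + 1e-7)])
}

## direct median-of-ratios formula
sf_oracle <- function(mat) {
  lg <- log(mat)
  geo <- rowMeans(lg)
  apply(lg, 2, function(col) exp(median((col - geo)[is.finite(geo)])))
}

## per-base membership of a set of 1-based closed intervals
perbase <- function(starts, ends, upto) {
  v <- logical(upto)
  for (q in seq_along(starts)) v[starts[q]:ends[q]] <- TRUE
  v
}

## tiny GTF writer for hand-built fixtures
write_toy_gtf <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
                     r$gene, ifelse(is.null(r$tx), paste0(r$gene, ".1"), r$tx),
                     ifelse(is.null(r$bt), "protein_coding", r$bt))
    paste(r$chrom, "toy", r$type, r$start, r$end, ".", r$strand, ".", attrs,
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

## constant-value coverage track over one chromosome
flat_track <- function(value, len, chrom = "chr1") {
  sl <- setNames(as.integer(len), chrom)
  mk <- function(v) {
    rl <- IRanges::RleList(S4Vectors::Rle(v, len))
    names(rl) <- chrom
    rl
  }
  coverage_track(mk(value), mk(0), sl, "stranded")
}

## track from an explicit per-base numeric vector (plus strand; minus zero)
vector_track <- function(v, chrom = "chr1", minus = NULL) {
  sl <- setNames(length(v), chrom)
  mk <- function(x) {
    rl <- IRanges::RleList(S4Vectors::Rle(x))
    names(rl) <- chrom
    rl
  }
  coverage_track(mk(v), mk(if (is.null(minus)) rep(0, length(v)) else minus),
                 sl, "stranded")
}
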