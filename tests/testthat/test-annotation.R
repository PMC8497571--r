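test_that("GTF parsing filters biotype and preserves coordinates", {
  gtf <- write_toy_gtf(withr::local_tempfile(fileext = ".gtf"), list(
    list(chrom = "chr1", type = "gene", start = 1, end = 100, strand = "+",
         gene = "gA"),
    list(chrom = "chr1", type = "exon", start = 1, end = 100, strand = "+",
         gene = "gA"),
    list(chrom = "chr1", type = "gene", start = 500, end = 900, strand = "-",
         gene = "gB"),
    list(chrom = "chr1", type = "exon", start = 500, end = 900, strand = "-",
         gene = "gB"),
    list(chrom = "chr1", type = "gene", start = 2000, end = 2500,
         strand = "+", gene = "gL", bt = "lincRNA"),
    list(chrom = "chr1", type = "exon", start = 2000, end = 2500,
         strand = "+", gene = "gL", bt = "lincRNA")))
  ann <- read_gene_annotation(gtf, biotype = "protein_coding")
  expect_equal(length(ann$genes), 2L)
  expect_setequal(ann$genes$gene_id, c("gA", "gB"))
  ## GTF 1-based inclusive kept as-is in the GRanges
  expect_equal(start(ann$genes[ann$genes$gene_id == "gA"]), 1L)
  expect_equal(end(ann$genes[ann$genes$gene_id == "gA"]), 100L)
  ## round-trip through the package's own writer is the identity on coordinates
  out <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, out)
  ann2 <- read_gene_annotation(out, biotype = "protein_coding")
  expect_equal(as.data.frame(ann2$genes), as.data.frame(ann$genes))
  expect_equal(as.data.frame(ann2$exons), as.data.frame(ann$exons))
})

test_that("malformed GTF lines fail with a line number", {
  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "toy", "gene", 1, 100, ".", "+", ".",
          'gene_id "g1"; transcript_id "g1.1"; gene_type "protein_coding";',
          sep = "\t"),
    "chr1\tbroken line"), bad)
  expect_error(read_gene_annotation(bad), "line 2")
})

test_that("exons outside their gene span are a validation error", {
  g <- make_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 100,
                             end = 200, strand = "+"))
  e <- GRanges("chr1", IRanges(150, 250), "+", gene_id = "g1",
               transcript_id = "g1.1")
  expect_error(gene_annotation(g, e), "outside")
})

test_that("exon classification unions positional labels across transcripts", {
  ## single-exon, single-transcript gene: both first and last, so never
  ## exclusively first
  g <- make_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 1,
                             end = 500, strand = "+"))
  e <- GRanges("chr1", IRanges(1, 500), "+", gene_id = "g1",
               transcript_id = "g1.1")
  cl <- classify_exons(gene_annotation(g, e))
  expect_true(cl$first & cl$last)
  expect_false(cl$internal)
  expect_false(cl$exclusively_first)

  ## exon first in T1 but internal in T2 -> labels {first, internal}
  g <- make_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 1,
                             end = 3000, strand = "+"))
  e <- GRanges("chr1",
               IRanges(c(1000, 2000,   100, 1000, 2000),
                       c(1400, 2500,   300, 1400, 2500)), "+",
               gene_id = "g1",
               transcript_id = c("t1", "t1", "t2", "t2", "t2"))
  cl <- classify_exons(gene_annotation(g, e))
  shared <- cl[cl$start == 1000, ]
  expect_true(shared$first & shared$internal)
  expect_false(shared$exclusively_first)
  ## t2's own first exon is first-only
  expect_true(cl$exclusively_first[cl$start == 100])
  ## a single-transcript k-exon gene yields one first, one last, k-2 internal
  g3 <- make_genes(data.frame(gene_id = "g3", chrom = "chr1", start = 1,
                              end = 5000, strand = "-"))
  e3 <- GRanges("chr1", IRanges(c(1, 1500, 3000, 4500),
                                c(900, 2000, 3500, 5000)), "-",
                gene_id = "g3", transcript_id = "g3.1")
  cl3 <- classify_exons(gene_annotation(g3, e3))
  ## minus strand: first exon is the rightmost
  expect_equal(cl3$start[cl3$first], 4500)
  expect_equal(cl3$start[cl3$last], 1)
  expect_equal(sum(cl3$internal), 2L)
})

test_that("exon classification matches an exhaustive per-transcript oracle", {
  for (seed in c(11, 12)) {
    sim <- simulate_annotation(sim_config(n_genes = 40, n_chromosomes = 2,
                                          multi_transcript_p = 0.6,
                                          seed = seed))
    cl <- classify_exons(sim$ann)
    ex <- sim$ann$exons
    df <- data.frame(gene = ex$gene_id, tx = ex$transcript_id,
                     start = start(ex), end = end(ex),
                     strand = as.character(strand(ex)))
    ## oracle: label each exon inside each transcript independently, then
    ## aggregate by any() per unique exon within a gene
    lab <- list()
    for (tx in unique(df$tx)) {
      sub <- df[df$tx == tx, ]
      sub <- sub[order(sub$start, decreasing = sub$strand[1] == "-"), ]
      for (r in seq_len(nrow(sub))) {
        key <- paste(sub$gene[r], sub$start[r], sub$end[r])
        cur <- lab[[key]]
        if (is.null(cur)) cur <- c(first = FALSE, internal = FALSE, last = FALSE)
        if (r == 1) cur["first"] <- TRUE
        if (r == nrow(sub)) cur["last"] <- TRUE
        if (r > 1 && r < nrow(sub)) cur["internal"] <- TRUE
        lab[[key]] <- cur
      }
    }
    expect_equal(nrow(cl), length(lab))
    expect_equal(attr(cl, "n_exon_annotations"), nrow(df))
    key_cl <- paste(cl$gene_id, cl$start, cl$end)
    for (k in seq_len(nrow(cl))) {
      expect_equal(unname(lab[[key_cl[k]]]),
                   unname(c(cl$first[k], cl$internal[k], cl$last[k])))
    }
    expect_equal(attr(cl, "n_exclusively_first"),
                 sum(vapply(lab, function(x)
                   x["first"] && !x["internal"] && !x["last"], logical(1))))
  }
})

test_that("intron derivation is the exact span/exon set difference", {
  ## single exon covering the whole locus -> no introns
  g <- make_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 1,
                             end = 400, strand = "+"))
  e <- GRanges("chr1", IRanges(1, 400), "+", gene_id = "g1",
               transcript_id = "g1.1")
  expect_length(derive_introns(gene_annotation(g, e)), 0L)

  ## gene 1..100 with exons 1..30 and 61..100 -> intron 31..60
  g <- make_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 1,
                             end = 100, strand = "+"))
  e <- GRanges("chr1", IRanges(c(1, 61), c(30, 100)), "+", gene_id = "g1",
               transcript_id = "g1.1")
  intr <- derive_introns(gene_annotation(g, e))
  expect_equal(start(intr), 31L)
  expect_equal(end(intr), 60L)

  ## three overlapping transcripts vs a naive per-base oracle, plus the
  ## partition invariant introns + exon-union == gene span
  g <- make_genes(data.frame(gene_id = "g1", chrom = "chr1", start = 101,
                             end = 1100, strand = "-"))
  set.seed(42)
  exs <- list()
  for (t in 1:3) {
    st <- sort(sample(101:1000, 3))
    en <- pmin(st + sample(30:150, 3, replace = TRUE), 1100)
    exs[[t]] <- GRanges("chr1", IRanges(c(101, st), c(120, en)), "-",
                        gene_id = "g1", transcript_id = paste0("t", t))
  }
  e <- c(exs[[1]], exs[[2]], exs[[3]])
  ## force the span to be covered at both ends
  e <- c(e, GRanges("chr1", IRanges(1050, 1100), "-", gene_id = "g1",
                    transcript_id = "t1"))
  ann <- gene_annotation(g, e)
  intr <- derive_introns(ann)
  covered <- perbase(start(e), end(e), 1100)
  is_intron <- logical(1100); is_intron[101:1100] <- !covered[101:1100]
  got <- logical(1100)
  if (length(intr)) got[unlist(Map(seq, start(intr), end(intr)))] <- TRUE
  expect_equal(got, is_intron)
  expect_equal(sum(width(intr)) + sum(covered[101:1100]), 1000)
})

test_that("promoter windows are strand-aware and clipped", {
  cfg <- analysis_config()
  mk <- function(pos, strand) {
    g <- make_genes(data.frame(gene_id = "g", chrom = "chr1",
                               start = ifelse(strand == "+", pos, pos - 2000),
                               end = ifelse(strand == "+", pos + 2000, pos),
                               strand = strand))
    e <- GRanges("chr1", IRanges(start(g), end(g)), strand, gene_id = "g",
                 transcript_id = "g.1")
    gene_annotation(g, e)
  }
  pw <- promoter_windows(mk(10001, "+"), cfg)
  expect_equal(c(start(pw), end(pw)), c(9101L, 10100L))
  pw <- promoter_windows(mk(10000, "-"), cfg)
  expect_equal(c(start(pw), end(pw)), c(9901L, 10900L))
  ## clipping at the chromosome start
  pw <- promoter_windows(mk(301, "+"), cfg)
  expect_equal(c(start(pw), end(pw)), c(1L, 400L))
})

test_that("enhancers are peaks with zero promoter overlap", {
  prom <- GRanges("chr1", IRanges(c(1000, 5000), c(2000, 6000)))
  peaks <- GRanges("chr1", IRanges(c(1200, 2000, 2001, 7000),
                                   c(1300, 2100, 2100, 7100)))
  enh <- define_enhancers(peaks, prom)
  ## fully inside and 1-bp-overlapping peaks are excluded
  expect_equal(start(enh), c(2001L, 7000L))
  expect_equal(enh$center, c(2050L, 7050L))
  ## no promoters -> identity
  expect_equal(length(define_enhancers(peaks, GRanges())), length(peaks))
  ## random peaks vs an all-pairs overlap oracle
  set.seed(9)
  ps <- sort(sample.int(50000, 50)); pe <- ps + sample(50:400, 50, replace = TRUE)
  qs <- sort(sample.int(50000, 10)); qe <- qs + sample(200:2000, 10, replace = TRUE)
  peaks <- GRanges("chr1", IRanges(ps, pe))
  prom <- GRanges("chr1", IRanges(qs, qe))
  keep_oracle <- vapply(seq_along(ps), function(i)
    !any(ps[i] <= qe & pe[i] >= qs), logical(1))
  expect_equal(start(define_enhancers(peaks, prom)), ps[keep_oracle])
})

test_that("interval merging equals the per-base union", {
  a <- GRanges("chr1", IRanges(1, 10))
  b <- GRanges("chr1", IRanges(5, 15))
  m <- merge_intervals(a, b)
  expect_equal(c(start(m), end(m)), c(1L, 15L))
  ## disjoint inputs unchanged
  d <- GRanges("chr1", IRanges(c(1, 100), c(10, 120)))
  expect_equal(as.data.frame(merge_intervals(d))[, 1:3],
               as.data.frame(d)[, 1:3])
  ## 100 random intervals vs per-base union oracle
  set.seed(17)
  st <- sample.int(5000, 100); en <- st + sample(1:200, 100, replace = TRUE)
  m <- merge_intervals(GRanges("chr1", IRanges(st, en)))
  v <- perbase(st, en, 6000)
  got <- logical(6000)
  got[unlist(Map(seq, start(m), end(m)))] <- TRUE
  expect_equal(got, v)
  expect_true(all(start(m)[-1] > end(m)[-length(m)] + 1L))
})
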