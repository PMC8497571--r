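## one simple gene annotation on a long chromosome, for metagene tests
mk_gene <- function(start, end, strand = "+", id = "g1", chrom = "chr1") {
  g <- make_genes(data.frame(gene_id = id, chrom = chrom, start = start,
                             end = end, strand = strand))
  e <- GRanges(chrom, IRanges(start, end), strand, gene_id = id,
               transcript_id = paste0(id, ".1"))
  gene_annotation(g, e)
}

test_that("scaled metagene preserves constants and exact-length genes", {
  cfg <- analysis_config()
  ann <- mk_gene(5001, 9000)          # 4000 bp > 1500 bp minimum
  tr <- flat_track(3, 20000)
  mat <- metagene_scaled(tr, ann, cfg)
  expect_equal(dim(mat), c(1L, 350L))
  expect_true(all(mat == 3))          # scaling preserves constant signal
  ## a gene of exactly unscaled5 + body + unscaled3 bp: scaling is the
  ## identity, so the matrix equals direct 10-bp binning of the raw signal
  set.seed(3)
  v <- numeric(20000)
  v[3001:8000] <- rpois(5000, 5)
  trv <- vector_track(v, "chr1")
  ann2 <- mk_gene(4001, 6000, id = "g2")   # 2000 = 1000 + 500 + 500
  mat2 <- metagene_scaled(trv, ann2, cfg)
  direct <- colMeans(matrix(v[3001:6500], nrow = 10))
  expect_equal(as.numeric(mat2[1, ]), direct)
})

test_that("scaled body equals a dense linear-interpolation oracle", {
  cfg <- analysis_config()
  ## triangular profile across a 4000 bp gene
  gene_start <- 5001; gene_end <- 9000
  v <- numeric(20000)
  L <- gene_end - gene_start + 1
  v[gene_start:gene_end] <- c(seq_len(L / 2), rev(seq_len(L / 2)))
  tr <- vector_track(v)
  mat <- metagene_scaled(tr, mk_gene(gene_start, gene_end), cfg)
  body_cols <- 201:250
  body_raw <- v[(gene_start + 1000):(gene_end - 500)]
  dense <- approx(seq_along(body_raw), body_raw,
                  xout = seq(1, length(body_raw), length.out = 500))$y
  oracle <- colMeans(matrix(dense, nrow = 10))
  ## agreement within one bin's worth of interpolation slack
  expect_lt(max(abs(as.numeric(mat[1, body_cols]) - oracle)), 1e-9)
  ## minus-strand genes are reversed so the TSS is on the left
  matm <- metagene_scaled(tr, mk_gene(gene_start, gene_end, "-"), cfg)
  flank5_minus <- as.numeric(matm[1, 1:100])
  expect_equal(flank5_minus,
               rev(colMeans(matrix(v[(gene_end + 1):(gene_end + 1000)], nrow = 10))))
})

test_that("metagene operations are linear in the track", {
  cfg <- analysis_config()
  set.seed(8)
  v1 <- rpois(20000, 2); v2 <- rpois(20000, 5)
  ann <- mk_gene(5001, 9000)
  m1 <- metagene_scaled(vector_track(v1), ann, cfg)
  m2 <- metagene_scaled(vector_track(v2), ann, cfg)
  m12 <- metagene_scaled(vector_track(3 * v1 + v2), ann, cfg)
  expect_equal(as.numeric(m12), as.numeric(3 * m1 + m2), tolerance = 1e-12)
})

test_that("short genes are dropped from scaled metagenes with a message", {
  cfg <- analysis_config()
  g <- make_genes(data.frame(gene_id = c("ok", "tiny"), chrom = "chr1",
                             start = c(5001, 12000), end = c(9000, 13000),
                             strand = "+"))
  e <- GRanges("chr1", IRanges(c(5001, 12000), c(9000, 13000)), "+",
               gene_id = c("ok", "tiny"),
               transcript_id = c("ok.1", "tiny.1"))
  ann <- gene_annotation(g, e)
  expect_message(mat <- metagene_scaled(flat_track(1, 20000), ann, cfg),
                 "dropped")
  expect_equal(rownames(mat), "ok")
})

test_that("reference-point windows are oriented and zero-padded", {
  ## delta signal at the anchor -> a single nonzero central bin
  v <- numeric(5000); v[2000] <- 7
  tr <- vector_track(v)
  anch <- GRanges("chr1", IRanges(2000, 2000), "+", gene_id = "g1")
  m <- metagene_refpoint(tr, anch, b = 500, a = 500, bin = 1)
  expect_equal(unname(which(m[1, ] != 0)), 501L)
  expect_equal(as.numeric(m[1, 501]), 7)
  ## minus-strand anchor mirrors an asymmetric profile
  v2 <- numeric(5000); v2[2001:2100] <- 1   # downstream of 2000 on plus
  anch_p <- GRanges("chr1", IRanges(2000, 2000), "+", gene_id = "p")
  anch_m <- GRanges("chr1", IRanges(2000, 2000), "-", gene_id = "m")
  tr2p <- vector_track(v2)
  tr2m <- vector_track(numeric(5000), minus = v2)
  mp <- metagene_refpoint(tr2p, anch_p, 500, 500, 1, signal = "sense")
  ## on the minus strand the same genomic stretch is upstream of the anchor
  mm <- metagene_refpoint(tr2m, anch_m, 500, 500, 1, signal = "sense")
  expect_equal(sum(mp[1, 502:601]), 100)
  expect_equal(sum(mm[1, 401:500]), 100)
  ## windows off the chromosome end are zero-padded, not dropped
  anch_edge <- GRanges("chr1", IRanges(100, 100), "+", gene_id = "e")
  me <- metagene_refpoint(tr, anch_edge, 500, 500, 1)
  expect_equal(ncol(me), 1000L)
  expect_true(all(me[1, 1:401] == 0))
  ## random track + anchors equal a direct slicing oracle
  set.seed(12)
  v3 <- rpois(5000, 3)
  tr3 <- vector_track(v3)
  pos <- sample(600:4400, 10)
  anch3 <- GRanges("chr1", IRanges(pos, pos), "+",
                   gene_id = sprintf("a%02d", 1:10))
  m3 <- metagene_refpoint(tr3, anch3, 500, 500, 1)
  for (i in 1:10)
    expect_equal(as.numeric(m3[i, ]), v3[(pos[i] - 500):(pos[i] + 499)])
})

test_that("travelling ratio follows the closed form and flags empty bodies", {
  cfg <- analysis_config()
  ## uniform coverage density d over a 2750 bp gene: TR = 250/(2750-250) = 0.1
  ann <- mk_gene(1001, 3750)
  tr <- flat_track(4, 10000)
  pt <- pausing_index(tr, ann, cfg)
  expect_equal(pt$travelling_ratio, 0.1)
  expect_false(pt$flagged)
  ## invariance to global track rescaling
  pt2 <- pausing_index(flat_track(400, 10000), ann, cfg)
  expect_equal(pt2$travelling_ratio, pt$travelling_ratio)
  ## all signal inside the promoter window: body is empty -> flagged Inf
  v <- numeric(10000); v[1001:1250] <- 2
  ptI <- pausing_index(vector_track(v), ann, cfg)
  expect_true(ptI$flagged)
  expect_equal(ptI$travelling_ratio, Inf)
  ## minus-strand gene: promoter window is at the right end
  vM <- numeric(10000); vM[3501:3750] <- 1   # 250 bp at the minus TSS
  annM <- mk_gene(1001, 3750, "-")
  ptM <- pausing_index(coverage_track(
    IRanges::RleList(chr1 = S4Vectors::Rle(numeric(10000))),
    IRanges::RleList(chr1 = S4Vectors::Rle(vM)),
    c(chr1 = 10000L), "stranded"), annM, cfg)
  expect_true(ptM$flagged)   # all signal promoter-proximal
  expect_equal(ptM$promoter_count, 250)
  ## genes shorter than the window are excluded with a message
  gshort <- make_genes(data.frame(gene_id = "s", chrom = "chr1", start = 1,
                                  end = 200, strand = "+"))
  eshort <- GRanges("chr1", IRanges(1, 200), "+", gene_id = "s",
                    transcript_id = "s.1")
  expect_message(ps <- pausing_index(tr, gene_annotation(gshort, eshort), cfg),
                 "excluded")
  expect_equal(nrow(ps), 0L)
})

test_that("planted travelling ratios are recovered from simulated reads", {
  cfg <- sim_config(n_genes = 120, n_chromosomes = 3, depth = 6e5, seed = 41)
  sim <- simulate_annotation(cfg)
  cov <- simulate_coverage(sim, "control", n_reps = 1)
  tr <- fragments_to_coverage(cov$fragments[[1]], sim$seqlengths)
  pt <- pausing_index(tr, sim$ann)
  m <- merge(pt[is.finite(pt$travelling_ratio), ],
             sim$truth[, c("gene_id", "true_TR")])
  expect_gt(nrow(m), 100)
  expect_gt(cor(m$travelling_ratio, m$true_TR, method = "spearman"), 0.9)
})

test_that("unchanged-gene normalization has the stated fixed points", {
  cfg <- analysis_config()
  set.seed(14)
  ## synthetic library: per-gene profiles with a TSS peak
  sim <- simulate_annotation(sim_config(n_genes = 60, n_chromosomes = 2,
                                        seed = 51))
  cov <- simulate_coverage(sim, "control", n_reps = 1)
  track <- fragments_to_coverage(cov$fragments[[1]], sim$seqlengths)
  mat <- metagene_scaled(track, sim$ann, cfg)
  ref <- rownames(mat)[1:20]
  norm <- normalize_polII(mat, ref)
  ly <- attr(mat, "layout")
  tss_cols <- c(ly$segments$flank5["start"]:ly$segments$flank5["end"],
                ly$segments$unscaled5["start"]:ly$segments$unscaled5["end"])
  ## self-normalization: reference TSS +/- 1 kb mean is exactly 1
  expect_equal(mean(norm[ref, tss_cols]), 1, tolerance = 1e-9)
  ## shift invariance: adding a constant to the track changes nothing
  shifted <- mat + 5
  attr(shifted, "layout") <- ly
  norm_s <- normalize_polII(shifted, ref)
  expect_equal(as.numeric(norm_s), as.numeric(norm), tolerance = 1e-9)
  ## affine pair: scale by s and offset k -> identical normalized matrices
  affine <- 2.7 * mat + 11
  attr(affine, "layout") <- ly
  norm_a <- normalize_polII(affine, ref)
  expect_equal(as.numeric(norm_a), as.numeric(norm), tolerance = 1e-9)
  ## idempotence: renormalizing returns the matrix with beta ~ 0, mu ~ 1
  norm2 <- normalize_polII(norm, ref)
  expect_equal(as.numeric(norm2), as.numeric(norm), tolerance = 1e-9)
  expect_equal(attr(norm2, "baseline"), 0, tolerance = 1e-9)
  expect_equal(attr(norm2, "tss_scale"), 1, tolerance = 1e-9)
  ## degenerate reference set errors out
  flat <- matrix(1, nrow = nrow(mat), ncol = ncol(mat),
                 dimnames = dimnames(mat))
  attr(flat, "layout") <- ly
  expect_error(normalize_polII(flat, ref), "degenerate")
})

test_that("unchanged-gene selection is deterministic and null-safe", {
  cfg <- analysis_config()
  ## all-null table with equal expression: deterministic gene_id tie-break
  de <- data.frame(gene_id = sprintf("g%02d", 20:1), mean_expression = 7,
                   log2FC = 0, padj = 1)
  expect_equal(select_unchanged_genes(de, 5, cfg), sprintf("g%02d", 1:5))
  ## a strongly changed gene is never selected
  de$log2FC[de$gene_id == "g03"] <- 2
  de$padj[de$gene_id == "g03"] <- 1e-6
  expect_false("g03" %in% select_unchanged_genes(de, 19, cfg))
  ## with noisy estimates the selection stays inside the true null set
  ok <- vapply(1:30, function(s) {
    set.seed(s)
    null_ids <- sprintf("n%03d", 1:300)
    alt_ids <- sprintf("a%03d", 1:100)
    tab <- data.frame(
      gene_id = c(null_ids, alt_ids),
      mean_expression = c(exp(rnorm(300, 6, 1)), exp(rnorm(100, 6, 1))),
      log2FC = c(rnorm(300, 0, 0.05), rnorm(100, sample(c(-1, 1), 100,
                                                        replace = TRUE), 0.2)),
      padj = c(runif(300, 0.3, 1), runif(100, 0, 0.05)))
    all(select_unchanged_genes(tab, 50, cfg) %in% null_ids)
  }, logical(1))
  expect_true(all(ok))
  ## asking for more genes than qualify warns and returns all
  expect_warning(got <- select_unchanged_genes(de, 50, cfg), "only")
  expect_equal(length(got), 19L)
})
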