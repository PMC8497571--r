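#' Simulation configuration
#'
#' Parameters of the synthetic genome and sequencing model used to verify
#' every analysis stage against known ground truth. The generator emulates
#' the statistical regime the analyses assume: a tunable fraction of
#' head-to-head (divergent) gene pairs at log-uniform TSS-TSS distances
#' below 1 kb, log-normal expression, a promoter-proximal pausing peak with
#' a per-gene log-normal travelling ratio, opposite-strand initiation
#' signal at divergent promoters, a per-gene intron/exon coverage ratio,
#' and a knock-down condition that preferentially represses high-expressed
#' divergent genes (with an intron-retention side effect on repressed
#' genes).
#'
#' @param ... named overrides of the defaults:
#' `n_genes` (1000), `n_chromosomes` (10), `fraction_divergent` (0.3),
#' `divergent_distance` (log-uniform range c(100, 900) bp TSS-TSS),
#' `gene_length` (uniform range c(2000, 6000) bp),
#' `intergenic_gap` (uniform range c(3000, 8000) bp),
#' `expression_meanlog`/`expression_sdlog` (log(100), 1; per-gene mean-read
#' weights), `tr_meanlog`/`tr_sdlog` (log(3), 0.5; travelling ratios),
#' `intron_ratio_meanlog`/`intron_ratio_sdlog` (log(0.1), 0.5),
#' `antisense_fraction_at_divergent` (0.9), `antisense_background` (0.05),
#' `antisense_strength` (0.1; antisense reads as a fraction of gene reads),
#' `multi_transcript_p` (0.3), `kd_mean_log2fc` (-1), `kd_sd_log2fc` (0.3),
#' `kd_expression_quantile` (0.5; knock-down targets are divergent genes
#' above this expression quantile), `kd_retention_factor` (1.5),
#' `depth` (5e5 reads/sample), `read_length` (50), `seed` (1).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 1000L,
    n_chromosomes = 10L,
    fraction_divergent = 0.3,
    divergent_distance = c(100, 900),
    gene_length = c(2000, 6000),
    intergenic_gap = c(3000, 8000),
    expression_meanlog = log(100),
    expression_sdlog = 1,
    tr_meanlog = log(3),
    tr_sdlog = 0.5,
    intron_ratio_meanlog = log(0.1),
    intron_ratio_sdlog = 0.5,
    antisense_fraction_at_divergent = 0.9,
    antisense_background = 0.05,
    antisense_strength = 0.1,
    multi_transcript_p = 0.3,
    kd_mean_log2fc = -1,
    kd_sd_log2fc = 0.3,
    kd_expression_quantile = 0.5,
    kd_retention_factor = 1.5,
    depth = 5e5,
    read_length = 50L,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$fraction_divergent >= 0, cfg$fraction_divergent <= 1,
            cfg$depth > 0, cfg$antisense_fraction_at_divergent >= 0,
            cfg$antisense_fraction_at_divergent <= 1,
            cfg$gene_length[1] > 1600, cfg$read_length > 0)
  class(cfg) <- "sim_config"
  cfg
}

## alternating exon/intron segment widths for one transcript
.exon_segments <- function(L, k) {
  if (k == 1L) return(list(exons = matrix(c(1L, L), ncol = 2)))
  nseg <- 2L * k - 1L
  base <- 300L
  extra <- L - base * nseg
  u <- runif(nseg)
  w <- base + floor(extra * u / sum(u))
  w[nseg] <- w[nseg] + (L - sum(w))
  ends <- cumsum(w)
  starts <- c(1L, head(ends, -1) + 1L)
  sel <- seq(1L, nseg, by = 2L)
  list(exons = cbind(starts[sel], ends[sel]))
}

#' Generate a synthetic annotation with ground truth
#'
#' Places genes on a synthetic genome with the requested fraction of
#' head-to-head divergent pairs at drawn TSS-TSS distances; all other genes
#' are isolated by large intergenic gaps. Each gene has 1-3 exons and, with
#' probability `multi_transcript_p`, a second transcript that skips the
#' first exon (so its second exon becomes a first exon in that transcript).
#' Per-gene expression, travelling ratio, intron/exon ratio, antisense
#' signal and knock-down effect are drawn as configured and recorded in the
#' truth table.
#'
#' @param cfg a [sim_config].
#' @return list with `ann` (a [gene_annotation]), `truth` (per-gene
#'   data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`,
#'   `is_divergent`, `partner_id`, `tss_distance`, `true_expression`,
#'   `true_TR`, `true_log2FC`, `true_intron_ratio`, `has_antisense_signal`),
#'   `seqlengths`, and `cfg`.
#' @export
simulate_annotation <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  n_pairs <- round(cfg$fraction_divergent * n / 2)
  n_single <- n - 2L * n_pairs
  ## unit list: TRUE = divergent pair (head-to-head), FALSE = singleton
  units <- sample(c(rep(TRUE, n_pairs), rep(FALSE, n_single)))
  nu <- length(units)
  unit_chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), nu))
  gaps <- round(runif(nu, cfg$intergenic_gap[1], cfg$intergenic_gap[2]))
  d <- round(exp(runif(nu, log(cfg$divergent_distance[1]),
                       log(cfg$divergent_distance[2]))))
  lenA <- round(runif(nu, cfg$gene_length[1], cfg$gene_length[2]))
  lenB <- round(runif(nu, cfg$gene_length[1], cfg$gene_length[2]))
  span <- ifelse(units, lenA + d + lenB - 1, lenA)
  pos <- numeric(nu)
  chrom_end <- numeric(cfg$n_chromosomes)
  for (ch in seq_len(cfg$n_chromosomes)) {
    ii <- which(unit_chrom == ch)
    if (!length(ii)) { chrom_end[ch] <- 1; next }
    cum <- cumsum(gaps[ii] + span[ii])
    pos[ii] <- 1 + cum - span[ii]
    chrom_end[ch] <- 1 + cum[length(cum)]
  }
  ## expand units into genes (pair: minus-strand gene A then plus-strand B)
  gene_unit <- rep(seq_len(nu), ifelse(units, 2L, 1L))
  is_B <- duplicated(gene_unit)
  u <- gene_unit
  gene_id <- sprintf("SYNG%05d", seq_along(gene_unit))
  sing_strand <- sample(c("+", "-"), nu, replace = TRUE)
  truth <- data.frame(
    gene_id = gene_id,
    chrom = paste0("chr", unit_chrom[u]),
    strand = ifelse(units[u], ifelse(is_B, "+", "-"), sing_strand[u]),
    start = ifelse(is_B, pos[u] + lenA[u] - 1 + d[u], pos[u]),
    is_divergent = units[u],
    partner_id = ifelse(units[u],
                        sprintf("SYNG%05d", seq_along(gene_unit) +
                                  ifelse(is_B, -1L, 1L)),
                        NA_character_),
    tss_distance = ifelse(units[u], d[u], NA_real_),
    stringsAsFactors = FALSE)
  truth$end <- truth$start + ifelse(is_B, lenB[u], lenA[u]) - 1
  truth$tss <- ifelse(truth$strand == "+", truth$start, truth$end)
  seqlengths <- setNames(as.integer(chrom_end + 10000L),
                         paste0("chr", seq_len(cfg$n_chromosomes)))
  ## per-gene latent parameters
  ng <- nrow(truth)
  truth$true_expression <- rlnorm(ng, cfg$expression_meanlog, cfg$expression_sdlog)
  truth$true_TR <- rlnorm(ng, cfg$tr_meanlog, cfg$tr_sdlog)
  truth$true_intron_ratio <- rlnorm(ng, cfg$intron_ratio_meanlog,
                                    cfg$intron_ratio_sdlog)
  truth$has_antisense_signal <- ifelse(
    truth$is_divergent,
    runif(ng) < cfg$antisense_fraction_at_divergent,
    runif(ng) < cfg$antisense_background)
  expr_cut <- quantile(truth$true_expression, cfg$kd_expression_quantile)
  target <- truth$is_divergent & truth$true_expression > expr_cut
  truth$true_log2FC <- ifelse(
    target, rnorm(ng, cfg$kd_mean_log2fc, cfg$kd_sd_log2fc), 0)
  ## exon structure: 1-3 exons; a second transcript (skipping the 5'-most
  ## exon) with probability multi_transcript_p
  k <- sample(1:3, ng, replace = TRUE)
  second <- k >= 2 & runif(ng) < cfg$multi_transcript_p
  acc_g <- acc_t <- acc_c <- acc_str <- acc_s <- acc_e <- vector("list", ng)
  for (i in seq_len(ng)) {
    L <- truth$end[i] - truth$start[i] + 1L
    seg <- .exon_segments(L, k[i])$exons
    st <- truth$start[i] + seg[, 1] - 1L
    en <- truth$start[i] + seg[, 2] - 1L
    m <- length(st)
    tids <- rep(paste0(truth$gene_id[i], ".1"), m)
    if (second[i]) {
      keep <- if (truth$strand[i] == "+") -1L else -m
      st <- c(st, st[keep]); en <- c(en, en[keep])
      tids <- c(tids, rep(paste0(truth$gene_id[i], ".2"), m - 1L))
    }
    acc_g[[i]] <- rep(truth$gene_id[i], length(st))
    acc_t[[i]] <- tids
    acc_c[[i]] <- rep(truth$chrom[i], length(st))
    acc_str[[i]] <- rep(truth$strand[i], length(st))
    acc_s[[i]] <- st; acc_e[[i]] <- en
  }
  exdf <- data.frame(
    gene_id = unlist(acc_g), transcript_id = unlist(acc_t),
    chrom = unlist(acc_c), strand = unlist(acc_str),
    start = unlist(acc_s), end = unlist(acc_e), stringsAsFactors = FALSE)
  genes <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start, truth$end), truth$strand,
    gene_id = truth$gene_id, gene_name = truth$gene_id,
    biotype = "protein_coding")
  exons <- GenomicRanges::GRanges(
    exdf$chrom, IRanges::IRanges(exdf$start, exdf$end), exdf$strand,
    gene_id = exdf$gene_id, transcript_id = exdf$transcript_id)
  GenomeInfoDb::seqlevels(genes) <- names(seqlengths)
  GenomeInfoDb::seqlengths(genes) <- seqlengths
  GenomeInfoDb::seqlevels(exons) <- names(seqlengths)
  GenomeInfoDb::seqlengths(exons) <- seqlengths
  ann <- gene_annotation(genes, exons)
  truth <- truth[match(ann$genes$gene_id, truth$gene_id), ]
  rownames(truth) <- NULL
  list(ann = ann, truth = truth, seqlengths = seqlengths, cfg = cfg)
}

## uniform read starts inside a set of intervals (matrix cols start,end),
## weighted by interval width; reads stay inside the widest possible span
.place_reads <- function(n, intervals, rl) {
  if (n == 0L || !nrow(intervals)) return(integer(0))
  w <- pmax(intervals[, 2] - intervals[, 1] + 1L - rl + 1L, 1L)
  pick <- sample.int(nrow(intervals), n, replace = TRUE, prob = w)
  intervals[pick, 1] + floor(runif(n) * w[pick])
}

#' Simulate stranded sequencing coverage and counts
#'
#' Draws Poisson read counts per gene at the configured depth (knock-down
#' condition multiplies expression by `2^true_log2FC`), splits reads into
#' promoter-proximal vs gene-body fractions to realize each gene's
#' travelling ratio, into exonic vs intronic fractions to realize its
#' intron/exon coverage ratio (repressed genes get the retention factor
#' applied under knock-down), and adds opposite-strand reads in the 100 nt
#' window upstream of the TSS for genes with antisense signal. Reads are
#' fragment intervals, not sequences.
#'
#' @param sim output of [simulate_annotation()].
#' @param condition `"control"` or `"knockdown"`.
#' @param n_reps number of replicates.
#' @param seed integer seed (default derived from the sim config seed and
#'   condition so the two conditions use independent draws).
#' @return list with `fragments` (per replicate, a stranded `GRanges`),
#'   `exon_counts`, `intron_counts` (genes x replicates integer matrices),
#'   `condition`, `seqlengths`.
#' @export
simulate_coverage <- function(sim, condition = c("control", "knockdown"),
                              n_reps = 2L, seed = NULL) {
  condition <- match.arg(condition)
  cfg <- sim$cfg; truth <- sim$truth
  if (is.null(seed))
    seed <- cfg$seed + ifelse(condition == "knockdown", 1000L, 0L)
  set.seed(seed)
  kd <- condition == "knockdown"
  rl <- cfg$read_length
  w <- truth$true_expression * if (kd) 2^truth$true_log2FC else 1
  lambda <- cfg$depth * w / sum(w)
  ## per-gene feature intervals as plain matrices (flat extraction; the
  ## per-gene loop below must not touch S4 containers)
  ng <- nrow(truth)
  introns <- derive_introns(sim$ann)
  intr_gid <- if (length(introns)) introns$gene_id else character(0)
  inm_all <- cbind(GenomicRanges::start(introns), GenomicRanges::end(introns))
  inm_by_gene <- lapply(seq_len(ng), function(i)
    inm_all[intr_gid == truth$gene_id[i], , drop = FALSE])
  ex <- sim$ann$exons
  exu <- GenomicRanges::reduce(GenomicRanges::split(
    GenomicRanges::granges(ex), factor(ex$gene_id, levels = truth$gene_id)))
  exf <- unlist(exu)
  ex_gid <- names(exf)
  exm_all <- cbind(GenomicRanges::start(exf), GenomicRanges::end(exf))
  exm_by_gene <- lapply(seq_len(ng), function(i)
    exm_all[ex_gid == truth$gene_id[i], , drop = FALSE])
  exon_counts <- intron_counts <- matrix(0L, ng, n_reps,
                                         dimnames = list(truth$gene_id, NULL))
  fragments <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    acc_start <- acc_chrom <- acc_strand <- vector("list", ng)
    for (i in seq_len(ng)) {
      n_i <- rpois(1, lambda[i])
      if (n_i == 0 && !truth$has_antisense_signal[i]) next
      exm <- exm_by_gene[[i]]
      inm <- inm_by_gene[[i]]
      Le <- sum(exm[, 2] - exm[, 1] + 1L)
      Li <- if (nrow(inm)) sum(inm[, 2] - inm[, 1] + 1L) else 0L
      r <- truth$true_intron_ratio[i] *
        if (kd && truth$true_log2FC[i] < 0) cfg$kd_retention_factor else 1
      f_i <- if (Li > 0) r * Li / (Le + r * Li) else 0
      n_intr <- rbinom(1, n_i, f_i)
      n_ex <- n_i - n_intr
      TR <- truth$true_TR[i]
      p_prom <- min(0.95, TR / ((1 + TR) * max(1 - f_i, 1e-6)))
      n_prom <- rbinom(1, n_ex, p_prom)
      n_body_ex <- n_ex - n_prom
      tss <- truth$tss[i]
      plus <- truth$strand[i] == "+"
      prom_iv <- if (plus) cbind(tss, tss + 249L) else cbind(tss - 249L, tss)
      ## body = exonic intervals beyond the promoter window
      body_ex <- exm
      if (plus) {
        body_ex[, 1] <- pmax(body_ex[, 1], tss + 250L)
      } else {
        body_ex[, 2] <- pmin(body_ex[, 2], tss - 250L)
      }
      body_ex <- body_ex[body_ex[, 2] > body_ex[, 1], , drop = FALSE]
      s_prom <- .place_reads(n_prom, prom_iv, rl)
      s_body <- .place_reads(n_body_ex, body_ex, rl)
      s_intr <- .place_reads(n_intr, inm, rl)
      n_sense <- length(s_prom) + length(s_body) + length(s_intr)
      exon_counts[i, rep_i] <- length(s_prom) + length(s_body)
      intron_counts[i, rep_i] <- length(s_intr)
      ## antisense initiation reads upstream of the TSS, opposite strand
      n_as <- if (truth$has_antisense_signal[i]) rpois(1, cfg$antisense_strength * lambda[i]) else 0L
      as_rl <- min(rl, 100L)
      as_iv <- if (plus) cbind(tss - 100L, tss - 1L) else cbind(tss + 1L, tss + 100L)
      s_as <- .place_reads(n_as, as_iv, as_rl)
      acc_start[[i]] <- c(s_prom, s_body, s_intr, s_as)
      acc_chrom[[i]] <- rep(truth$chrom[i], n_sense + length(s_as))
      acc_strand[[i]] <- c(rep(truth$strand[i], n_sense),
                           rep(if (plus) "-" else "+", length(s_as)))
    }
    gr <- GenomicRanges::GRanges(
      unlist(acc_chrom), IRanges::IRanges(unlist(acc_start), width = rl),
      unlist(acc_strand))
    GenomeInfoDb::seqlevels(gr) <- names(sim$seqlengths)
    GenomeInfoDb::seqlengths(gr) <- sim$seqlengths
    gr <- GenomicRanges::trim(gr)
    fragments[[rep_i]] <- sort(gr)
  }
  list(fragments = fragments, exon_counts = exon_counts,
       intron_counts = intron_counts, condition = condition,
       seqlengths = sim$seqlengths)
}

#' Simple differential-expression table from simulated counts
#'
#' Per-gene log2 fold-change of size-factor-normalized mean counts (with a
#' 0.5 pseudocount) between two conditions, with an exact conditional
#' binomial test on the summed raw counts (success probability from the
#' library totals) and Benjamini-Hochberg adjustment. A deliberately simple
#' stand-in for a negative-binomial DE model, adequate for the simulated
#' Poisson counts.
#'
#' @param counts_ctrl,counts_cond integer matrices (genes x replicates),
#'   same rownames.
#' @return data.frame `gene_id`, `mean_expression` (mean normalized count),
#'   `log2FC`, `pvalue`, `padj`.
#' @export
simulate_de_table <- function(counts_ctrl, counts_cond) {
  stopifnot(nrow(counts_ctrl) == nrow(counts_cond),
            identical(rownames(counts_ctrl), rownames(counts_cond)))
  if (ncol(counts_ctrl) < 2 || ncol(counts_cond) < 2)
    stop("need >= 2 replicates per condition")
  all_counts <- cbind(counts_ctrl, counts_cond)
  sf <- size_factors(all_counts)
  norm <- sweep(all_counts, 2, sf, "/")
  i_ctrl <- seq_len(ncol(counts_ctrl))
  m_ctrl <- rowMeans(norm[, i_ctrl, drop = FALSE])
  m_cond <- rowMeans(norm[, -i_ctrl, drop = FALSE])
  log2fc <- log2((m_cond + 0.5) / (m_ctrl + 0.5))
  x_cond <- rowSums(counts_cond)
  x_tot <- x_cond + rowSums(counts_ctrl)
  ## null success probability from size-factor shares, so composition
  ## shifts (strongly repressed genes inflating the rest) do not bias the test
  p0 <- sum(sf[-i_ctrl]) / sum(sf)
  pv <- vapply(seq_along(x_tot), function(i) {
    if (x_tot[i] == 0) return(1)
    binom.test(x_cond[i], x_tot[i], p = p0)$p.value
  }, numeric(1))
  data.frame(gene_id = rownames(all_counts),
             mean_expression = rowMeans(norm),
             log2FC = log2fc, pvalue = pv,
             padj = p.adjust(pv, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Emits the annotation as Gencode-style GTF, per-condition stranded
#' bedGraph pairs (replicate 1), exon/intron count TSVs, the truth table
#' and the configuration as JSON — every file round-trips through the
#' package's own readers.
#'
#' @param sim output of [simulate_annotation()].
#' @param cov_ctrl,cov_kd outputs of [simulate_coverage()] for the two
#'   conditions.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(sim, cov_ctrl, cov_kd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "sim_config.json"))
  write_gtf(sim$ann, paths["gtf"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(unclass(sim$cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  for (cond in list(list(cov = cov_ctrl, tag = "control"),
                    list(cov = cov_kd, tag = "knockdown"))) {
    tr <- fragments_to_coverage(cond$cov$fragments[[1]], sim$seqlengths)
    p <- file.path(dir, paste0(cond$tag, c(".plus.bedgraph", ".minus.bedgraph")))
    write_bedgraph_pair(tr, p[1], p[2])
    for (what in c("exon_counts", "intron_counts")) {
      f <- file.path(dir, paste0(cond$tag, "_", what, ".tsv"))
      write.table(data.frame(gene_id = rownames(cond$cov[[what]]),
                             cond$cov[[what]], check.names = FALSE),
                  f, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[paste0(cond$tag, "_", what)] <- f
    }
    paths[paste0(cond$tag, "_plus")] <- p[1]
    paths[paste0(cond$tag, "_minus")] <- p[2]
  }
  invisible(paths)
}

#' Write a gene annotation as a Gencode-style GTF
#'
#' Emits gene, transcript and exon records with `gene_id`, `gene_name`,
#' `gene_type` and `transcript_id` attributes, converting back to GTF
#' 1-based inclusive coordinates (identity round-trip with
#' [read_gene_annotation()]).
#'
#' @param ann a [gene_annotation].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(ann, path) {
  g <- ann$genes; e <- ann$exons
  fmt <- function(chrom, src, type, start, end, strand, attrs)
    paste(chrom, src, type, start, end, ".", strand, ".", attrs,
          sep = "\t")
  gl <- fmt(as.character(GenomicRanges::seqnames(g)), "bipair", "gene",
            GenomicRanges::start(g), GenomicRanges::end(g),
            as.character(GenomicRanges::strand(g)),
            sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";',
                    g$gene_id, g$biotype, g$gene_name))
  tx <- unique(data.frame(gene_id = e$gene_id, transcript_id = e$transcript_id,
                          stringsAsFactors = FALSE))
  sp <- split(seq_along(e), e$transcript_id)
  tx_start <- vapply(sp, function(ii) min(GenomicRanges::start(e)[ii]), numeric(1))
  tx_end <- vapply(sp, function(ii) max(GenomicRanges::end(e)[ii]), numeric(1))
  gmatch <- match(tx$gene_id, g$gene_id)
  tmatch <- match(tx$transcript_id, names(sp))
  tl <- fmt(as.character(GenomicRanges::seqnames(g))[gmatch], "bipair",
            "transcript", tx_start[tmatch], tx_end[tmatch],
            as.character(GenomicRanges::strand(g))[gmatch],
            sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
                    tx$gene_id, tx$transcript_id, g$biotype[gmatch]))
  ematch <- match(e$gene_id, g$gene_id)
  el <- fmt(as.character(GenomicRanges::seqnames(e)), "bipair", "exon",
            GenomicRanges::start(e), GenomicRanges::end(e),
            as.character(GenomicRanges::strand(e)),
            sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
                    e$gene_id, e$transcript_id, g$biotype[ematch]))
  writeLines(c("##description: synthetic annotation (bipair)", gl, tl, el), path)
  invisible(path)
}
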