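#' Classify genes as up/down/unchanged from a DE table
#'
#' Applies the class thresholds with strict inequalities: `up` when
#' `log2FC > cfg$de_fc_min` and `padj < cfg$de_padj_max`; `down` mirrored
#' (`log2FC < -de_fc_min`, same padj cut); everything else `unchanged`.
#' Genes with missing padj are left unclassified (`NA`) with a message.
#'
#' @param de data.frame with columns `gene_id`, `mean_expression`, `log2FC`,
#'   `padj` (padj in `[0, 1]` or `NA`).
#' @param cfg an [analysis_config].
#' @return The input with a `class` factor column added
#'   (levels up/down/unchanged); class counts in attribute `class_counts`.
#' @export
classify_de <- function(de, cfg = analysis_config()) {
  stopifnot(all(c("gene_id", "log2FC", "padj") %in% names(de)))
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene ids in DE table")
  if (any(!is.na(de$padj) & (de$padj < 0 | de$padj > 1)))
    stop("padj outside [0, 1]")
  cls <- rep(NA_character_, nrow(de))
  known <- !is.na(de$padj) & !is.na(de$log2FC)
  if (any(!known))
    message(sum(!known), " gene(s) with missing padj/log2FC left unclassified")
  sig <- known & de$padj < cfg$de_padj_max
  cls[known] <- "unchanged"
  cls[sig & de$log2FC > cfg$de_fc_min] <- "up"
  cls[sig & de$log2FC < -cfg$de_fc_min] <- "down"
  de$class <- factor(cls, levels = c("up", "down", "unchanged"))
  attr(de, "class_counts") <- table(de$class, useNA = "ifany")
  de
}

#' Fold enrichment of a pair category in a DE class
#'
#' Compares the fraction of genes in a DE class that have a neighbour in
#' the given category (within the distance threshold) against the same
#' fraction in the full gene universe, and tests the 2x2 contingency table
#' (class membership x neighbour status, class vs rest of universe) with
#' a two-sided Fisher's exact test.
#'
#' @param pairs output of [annotate_pairs()].
#' @param class_genes character vector of gene ids in the DE class.
#' @param category one of `"upstream_antisense"`, `"upstream_sense"`,
#'   `"downstream_antisense"`, `"downstream_sense"`.
#' @param universe character vector of gene ids; defaults to all genes in
#'   `pairs`.
#' @return list with `fold`, `table` (2x2 matrix), `p_value`,
#'   `class_fraction`, `universe_fraction`.
#' @export
fold_enrichment <- function(pairs, class_genes,
                            category = "upstream_antisense",
                            universe = NULL) {
  col <- paste0(category, "_within")
  if (!col %in% names(pairs)) stop("unknown category: ", category)
  if (is.null(universe)) universe <- pairs$gene_id
  pairs <- pairs[pairs$gene_id %in% universe, , drop = FALSE]
  class_genes <- intersect(class_genes, pairs$gene_id)
  if (!length(class_genes)) stop("empty DE class after intersecting with universe")
  in_class <- pairs$gene_id %in% class_genes
  has <- pairs[[col]]
  tab <- matrix(c(sum(in_class & has), sum(in_class & !has),
                  sum(!in_class & has), sum(!in_class & !has)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("class", "rest"), c("has", "lacks")))
  class_frac <- mean(has[in_class])
  univ_frac <- mean(has)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(fold = class_frac / univ_frac, table = tab, p_value = ft$p.value,
       class_fraction = class_frac, universe_fraction = univ_frac)
}

#' Resampling null band for metagene profiles
#'
#' Confidence envelope of the per-column mean profile of random gene
#' subsets: draws `n_iter` subsets of `subset_size` rows without
#' replacement, computes each subset's column-mean profile, and takes
#' per-column nearest-rank percentiles at `(1 - ci) / 2` and
#' `1 - (1 - ci) / 2` (defaults: 10,000 draws, 99.9% band). An observed
#' class profile lying outside the band marks positions of genuine signal.
#'
#' Reproducible bit-exactly for a fixed `seed`; with
#' `subset_size = nrow(mat)` the band collapses onto the global mean.
#'
#' @param mat a metagene matrix (genes x bins).
#' @param subset_size rows per draw (e.g. the DE class size).
#' @param cfg an [analysis_config] (`n_resample`, `ci_level`).
#' @param seed integer RNG seed.
#' @return An object of class `"null_band"`: list with `lower`, `upper`
#'   (per-column bounds), `mean` (global mean profile), `n_iter`,
#'   `ci_level`, `subset_size`, `seed`.
#' @export
resample_null_band <- function(mat, subset_size, cfg = analysis_config(),
                               seed = cfg$rng_seed) {
  n <- nrow(mat)
  if (subset_size < 1) stop("subset_size must be >= 1")
  if (subset_size > n) stop("subset_size exceeds number of rows")
  n_iter <- cfg$n_resample
  set.seed(seed)
  prof <- matrix(0, nrow = n_iter, ncol = ncol(mat))
  for (i in seq_len(n_iter)) {
    prof[i, ] <- colMeans(mat[sample.int(n, subset_size), , drop = FALSE])
  }
  alpha <- (1 - cfg$ci_level) / 2
  lo_idx <- max(1L, ceiling(alpha * n_iter))
  hi_idx <- ceiling((1 - alpha) * n_iter)
  sorted <- apply(prof, 2, sort)
  structure(list(lower = sorted[lo_idx, ], upper = sorted[hi_idx, ],
                 mean = colMeans(mat), n_iter = n_iter,
                 ci_level = cfg$ci_level, subset_size = subset_size,
                 seed = seed),
            class = "null_band")
}

#' Flag profile positions outside a null band
#'
#' @param band a [resample_null_band()] result.
#' @param profile numeric vector (e.g. the column-mean profile of a DE
#'   class), same length as the band.
#' @return logical vector: `TRUE` where the profile lies strictly outside
#'   the band.
#' @export
outside_band <- function(band, profile) {
  stopifnot(inherits(band, "null_band"), length(profile) == length(band$lower))
  profile < band$lower | profile > band$upper
}

#' @export
print.null_band <- function(x, ...) {
  cat(sprintf("null_band: %d draws of %d genes, %.1f%% CI over %d positions\n",
              x$n_iter, x$subset_size, 100 * x$ci_level, length(x$lower)))
  invisible(x)
}

#' Expression ECDFs for gene sets
#'
#' Cumulative relative frequency of (log10-scaled) read counts per gene
#' set, plus the Kolmogorov-Smirnov D statistic between each pair of sets
#' (computed directly from the two ECDFs; D is invariant to the monotone
#' log transform).
#'
#' @param counts named numeric vector of per-gene counts (names = gene ids).
#' @param gene_sets named list of character vectors.
#' @return list with `curves` (per set, a data.frame `log10_count`,
#'   `cum_freq`) and `ks_D` (matrix of pairwise D statistics).
#' @export
expression_ecdf <- function(counts, gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1)
  if (is.null(names(counts))) stop("counts must be named by gene id")
  vals <- lapply(gene_sets, function(g) {
    v <- counts[intersect(g, names(counts))]
    if (!length(v)) stop("empty gene set")
    sort(log10(as.numeric(v) + 1))
  })
  curves <- lapply(vals, function(v)
    data.frame(log10_count = v, cum_freq = seq_along(v) / length(v)))
  k <- length(vals)
  D <- matrix(0, k, k, dimnames = list(names(gene_sets), names(gene_sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      grid <- sort(unique(c(vals[[i]], vals[[j]])))
      Fi <- stats::ecdf(vals[[i]])(grid)
      Fj <- stats::ecdf(vals[[j]])(grid)
      D[i, j] <- D[j, i] <- max(abs(Fi - Fj))
    }
  }
  list(curves = curves, ks_D = D)
}

#' Share of a DE class carrying an annotation tag
#'
#' Fraction of class genes present in a user-supplied tag list (e.g. the
#' fraction of repressed genes that are histone genes).
#'
#' @param class_genes character vector of gene ids.
#' @param tag_genes character vector of tagged gene ids.
#' @return numeric fraction `|class intersect tag| / |class|`.
#' @export
category_share <- function(class_genes, tag_genes) {
  if (!length(class_genes)) return(NA_real_)
  length(intersect(class_genes, tag_genes)) / length(unique(class_genes))
}
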