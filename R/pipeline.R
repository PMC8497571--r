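#' Read a DE results table
#'
#' TSV with columns `gene_id`, `mean_expression`, `log2FC`, `padj`
#' (additional columns kept).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  de <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "mean_expression", "log2FC", "padj")
  miss <- setdiff(need, names(de))
  if (length(miss)) stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
  de
}

#' Read a count matrix TSV
#'
#' First column `gene_id`, remaining columns one sample each
#' (featureCounts-style layout).
#'
#' @param path TSV file.
#' @return integer matrix with gene ids as rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Total exonic and intronic feature lengths per gene
#'
#' Exonic length is the width of the per-gene exon union; intronic length
#' the width of the derived introns (zero for intronless genes). These are
#' the feature lengths entering [intron_exon_ratio()].
#'
#' @param ann a [gene_annotation].
#' @return data.frame `gene_id`, `exon_length`, `intron_length`.
#' @export
feature_lengths <- function(ann) {
  ex <- ann$exons
  exu <- GenomicRanges::reduce(GenomicRanges::split(
    GenomicRanges::granges(ex), factor(ex$gene_id, levels = ann$genes$gene_id)))
  exon_len <- sum(IRanges::width(exu))   # per-element sums over the list
  intr <- derive_introns(ann)
  intron_len <- setNames(numeric(length(ann$genes)), ann$genes$gene_id)
  if (length(intr)) {
    s <- tapply(GenomicRanges::width(intr), intr$gene_id, sum)
    intron_len[names(s)] <- s
  }
  data.frame(gene_id = ann$genes$gene_id, exon_length = as.numeric(exon_len),
             intron_length = as.numeric(intron_len), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the full downstream analysis on a dataset directory
#'
#' Chains the analysis stages on a dataset laid out as written by
#' [write_dataset()]: annotation parsing, exon classification and intron
#' derivation, gene-pair annotation with per-class frequencies,
#' bidirectional-promoter calls from the control antisense coverage, the
#' travelling-ratio table, intron/exon ratios per condition, DE
#' classification and fold enrichment of the four pair categories for the
#' down- and upregulated classes. All result tables are written as TSV plus
#' a JSON summary and a run manifest (config snapshot, input checksums,
#' package version) to `out_dir`.
#'
#' Reruns on identical inputs produce identical outputs; the manifest
#' records input MD5 checksums so this can be verified.
#'
#' @param data_dir dataset directory ([write_dataset()] layout); must
#'   contain `annotation.gtf`, per-condition count TSVs and bedGraph pairs.
#' @param de DE table (data.frame or TSV path). When `NULL`, a table is
#'   derived from the exon counts with [simulate_de_table()].
#' @param out_dir output directory.
#' @param cfg an [analysis_config].
#' @return Invisibly, a list with the main result objects
#'   (`pairs`, `frequencies`, `enrichment`, `ratios`, `de`, `bidir`,
#'   `pausing`, `manifest`).
#' @export
run_pipeline <- function(data_dir, out_dir, de = NULL,
                         cfg = analysis_config()) {
  inputs <- c(gtf = file.path(data_dir, "annotation.gtf"),
              ctrl_exon = file.path(data_dir, "control_exon_counts.tsv"),
              ctrl_intron = file.path(data_dir, "control_intron_counts.tsv"),
              kd_exon = file.path(data_dir, "knockdown_exon_counts.tsv"),
              kd_intron = file.path(data_dir, "knockdown_intron_counts.tsv"),
              ctrl_plus = file.path(data_dir, "control.plus.bedgraph"),
              ctrl_minus = file.path(data_dir, "control.minus.bedgraph"))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (is.character(de)) de <- read_de_table(de)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ann <- read_gene_annotation(inputs["gtf"], biotype = "protein_coding")
  excls <- classify_exons(ann)
  flen <- feature_lengths(ann)
  pairs <- annotate_pairs(ann, cfg)

  ctrl_exon <- read_count_matrix(inputs["ctrl_exon"])
  ctrl_intron <- read_count_matrix(inputs["ctrl_intron"])
  kd_exon <- read_count_matrix(inputs["kd_exon"])
  kd_intron <- read_count_matrix(inputs["kd_intron"])
  if (is.null(de)) de <- simulate_de_table(ctrl_exon, kd_exon)
  de <- classify_de(de, cfg)

  seqlen_from <- function(ann) GenomeInfoDb::seqlengths(ann$genes)
  track <- read_bedgraph_pair(inputs["ctrl_plus"], inputs["ctrl_minus"],
                              seqlen_from(ann))
  bidir <- call_bidirectional(ann, track, cfg)
  pausing <- pausing_index(track, ann, cfg)

  gl <- setNames(flen$exon_length, flen$gene_id)
  il <- setNames(flen$intron_length, flen$gene_id)
  ord <- rownames(ctrl_exon)
  ratios_ctrl <- intron_exon_ratio(ctrl_exon, ctrl_intron, gl[ord], il[ord],
                                   cfg = cfg)
  ratios_kd <- intron_exon_ratio(kd_exon, kd_intron, gl[ord], il[ord],
                                 cfg = cfg)
  rfc <- ratio_vs_fc(ratios_ctrl, ratios_kd, de)

  classes <- list(down = de$gene_id[!is.na(de$class) & de$class == "down"],
                  up = de$gene_id[!is.na(de$class) & de$class == "up"])
  cats <- c("upstream_antisense", "upstream_sense",
            "downstream_antisense", "downstream_sense")
  enrich <- list()
  for (cl in names(classes)) {
    if (!length(classes[[cl]])) next
    for (cat in cats) {
      enrich[[paste(cl, cat, sep = ".")]] <-
        fold_enrichment(pairs, classes[[cl]], cat)
    }
  }
  freqs <- rbind(all = pair_frequencies(pairs),
                 down = if (length(classes$down))
                   pair_frequencies(pairs, classes$down) else NA,
                 up = if (length(classes$up))
                   pair_frequencies(pairs, classes$up) else NA)

  wr <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wr(excls, "exon_classification.tsv")
  wr(pairs, "pair_annotation.tsv")
  wr(bidir, "bidirectional_calls.tsv")
  wr(pausing, "pausing_index.tsv")
  wr(ratios_ctrl, "intron_exon_ratio_control.tsv")
  wr(ratios_kd, "intron_exon_ratio_knockdown.tsv")
  wr(de, "de_classified.tsv")
  summary <- list(
    n_genes = length(ann$genes),
    n_exon_annotations = attr(excls, "n_exon_annotations"),
    n_exclusively_first = attr(excls, "n_exclusively_first"),
    class_counts = as.list(table(as.character(de$class))),
    pair_frequencies = as.data.frame(freqs),
    enrichment = lapply(enrich, function(e)
      list(fold = e$fold, p_value = e$p_value)),
    ratio_fc_spearman = rfc$rho,
    bidirectional_fraction = mean(bidir$bidirectional))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       force = TRUE)
  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(packageVersion("bipair")),
    config = unclass(cfg),
    inputs = as.list(tools::md5sum(unname(inputs))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(ann = ann, pairs = pairs, frequencies = freqs,
                 enrichment = enrich, ratios = list(control = ratios_ctrl,
                                                    knockdown = ratios_kd,
                                                    vs_fc = rfc),
                 de = de, bidir = bidir, pausing = pausing,
                 manifest = manifest))
}
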