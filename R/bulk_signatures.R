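# Bulk RNA-seq signature derivation.
#
# FPKM tables are upper-quartile normalized: each sample is scaled so its
# 75th percentile over genes with value > 0 equals the geometric mean of
# all samples' upper quartiles, then log2(x + pseudocount) transformed.
# LSC/blast specificity keeps protein-coding genes with FPKM above the
# floor in either group and assigns each gene to the group with the higher
# normalized mean when the linear fold-change exceeds the threshold.

#' Per-sample upper-quartile scaling factors
#' @noRd
uq_factors <- function(values) {
  q <- vapply(seq_len(ncol(values)), function(j) {
    nz <- values[, j][values[, j] > 0]
    if (!length(nz))
      abort("sample '%s' has all-zero values; cannot normalize",
            colnames(values)[j])
    quantile(nz, 0.75, names = FALSE)
  }, numeric(1))
  geo_mean(q) / q
}

#' Upper-quartile normalize and log-transform a bulk table
#'
#' Scales each sample so its upper quartile (75th percentile over genes
#' with value > 0) equals the geometric mean of all samples' upper
#' quartiles, then applies log2(x + pseudocount).
#'
#' @param table an [expr_table()] with raw FPKM values.
#' @param pseudocount added before the log (default 1).
#' @return An [expr_table()] with state `"lognorm"`.
#' @export
normalize_bulk <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "expr_table"))
  if (table$state != "raw") abort("table is already normalized")
  f <- uq_factors(table$values)
  vals <- log2p(sweep(table$values, 2, f, "*"), pseudocount)
  out <- expr_table(vals, table$groups, table$coding, state = "lognorm")
  attr(out, "uq_factors") <- f
  out
}

#' Group means of a table's values
#' @noRd
group_means <- function(values, groups) {
  gs <- unique(groups)
  out <- vapply(gs, function(g)
    rowMeans(values[, groups == g, drop = FALSE]), numeric(nrow(values)))
  colnames(out) <- gs
  out
}

#' Derive LSC and blast gene signatures from sorted bulk RNA-seq
#'
#' Keeps protein-coding genes whose raw FPKM group mean exceeds
#' `fpkm_floor` in either the LSC or the blast samples, upper-quartile
#' normalizes, and assigns each retained gene to the cell type with the
#' higher normalized mean when the linear fold-change between the group
#' means exceeds `fc_threshold` (default 1: any difference; set 2 for a
#' stricter 2-fold call).
#'
#' @param table an [expr_table()] of raw FPKM with groups "LSC" and
#'   "Blast".
#' @param fpkm_floor expression floor on raw group-mean FPKM (default 1).
#' @param fc_threshold linear fold-change threshold, strict `>` (default 1).
#' @param lsc_label,blast_label group labels (defaults "LSC"/"Blast").
#' @return list of two [gene_signature()]s (`lsc`, `blast`); `log2fc` is
#'   signed toward the signature's own group.
#' @export
derive_lsc_blast_signature <- function(table, fpkm_floor = 1,
                                       fc_threshold = 1,
                                       lsc_label = "LSC",
                                       blast_label = "Blast") {
  stopifnot(inherits(table, "expr_table"))
  if (!all(c(lsc_label, blast_label) %in% table$groups))
    abort("table must contain groups '%s' and '%s'", lsc_label, blast_label)
  raw_means <- group_means(table$values, table$groups)
  keep <- table$coding &
    (raw_means[, lsc_label] > fpkm_floor |
       raw_means[, blast_label] > fpkm_floor)
  # specificity is decided on upper-quartile-normalized linear means: the
  # ratio is then exactly invariant to rescaling any single sample
  f <- uq_factors(table$values)
  lin <- sweep(table$values[keep, , drop = FALSE], 2, f, "*")
  m <- group_means(lin, table$groups)
  log2fc <- log2((m[, lsc_label] + 1e-12) / (m[, blast_label] + 1e-12))
  genes <- rownames(table$values)[keep]
  lsc_sel <- m[, lsc_label] > fc_threshold * m[, blast_label]
  blast_sel <- m[, blast_label] > fc_threshold * m[, lsc_label]
  list(lsc = gene_signature("LSC", genes[lsc_sel], log2fc[lsc_sel]),
       blast = gene_signature("Blast", genes[blast_sel], -log2fc[blast_sel]))
}

#' Rank all genes by between-group log2 fold-change
#'
#' Produces the preranked list used for cluster classification: genes
#' ranked by log2 fold-change of `group_a` over `group_b` on linearized
#' upper-quartile-normalized values, sorted descending with lexicographic
#' gene-id tie-break.
#'
#' @param table an [expr_table()] of raw values.
#' @param group_a,group_b group labels; positive scores mean higher in
#'   `group_a`.
#' @param floor small offset guarding against zero means (default 1e-9).
#' @return named numeric vector (gene -> log2FC), sorted descending.
#' @export
rank_genes <- function(table, group_a = "Blast", group_b = "LSC",
                       floor = 1e-9) {
  stopifnot(inherits(table, "expr_table"))
  if (!all(c(group_a, group_b) %in% table$groups))
    abort("groups '%s'/'%s' not both present", group_a, group_b)
  f <- uq_factors(table$values)
  lin <- sweep(table$values, 2, f, "*")
  m <- group_means(lin, table$groups)
  fc <- log2((m[, group_a] + floor) / (m[, group_b] + floor))
  fc <- setNames(as.numeric(fc), rownames(table$values))
  fc[order(-fc, names(fc))]
}

#' Derive subtype-specific genes (all-versus-each rule)
#'
#' A gene is subtype-specific when its target-group mean (upper-quartile
#' normalized, linear scale) is at least `fold` times the mean of every
#' other group individually — not the pooled mean. The comparison is
#' inclusive (`>=`).
#'
#' @param table an [expr_table()] of raw FPKM with >= 2 groups.
#' @param target_group the subtype of interest (e.g. "t821").
#' @param fold linear fold threshold (default 2).
#' @return A [gene_signature()]; `log2fc` is the log2 ratio of the target
#'   mean to the strongest other group's mean.
#' @export
derive_subtype_specific_genes <- function(table, target_group, fold = 2) {
  stopifnot(inherits(table, "expr_table"))
  if (!target_group %in% table$groups)
    abort("target group '%s' absent from table", target_group)
  if (length(unique(table$groups)) < 2L)
    abort("need at least 2 groups")
  f <- uq_factors(table$values)
  lin <- sweep(table$values, 2, f, "*")
  m <- group_means(lin, table$groups)
  others <- setdiff(colnames(m), target_group)
  max_other <- apply(m[, others, drop = FALSE], 1, max)
  sel <- m[, target_group] >= fold * max_other
  log2fc <- log2((m[sel, target_group] + 1e-9) / (max_other[sel] + 1e-9))
  gene_signature(paste0(target_group, "-specific"),
                 rownames(table$values)[sel], log2fc)
}

#' Write a gene signature as two-column TSV (+ JSON metadata)
#'
#' @param sig a [gene_signature()].
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(sig, path) {
  write.table(data.frame(gene = sig$genes, log2fc = sig$log2fc),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(name = sig$name, n_genes = length(sig$genes)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a gene signature written by [write_signature()]
#'
#' @param path TSV path.
#' @param name signature label; taken from the side-car JSON if present.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (is.null(name)) {
    meta <- paste0(path, ".json")
    name <- if (file.exists(meta))
      jsonlite::read_json(meta)$name else basename(path)
  }
  gene_signature(name, df$gene, df$log2fc)
}
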