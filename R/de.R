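# Fold-change differential expression for count tables.

#' Fold-change differential expression between two sample groups
#'
#' Genes with fewer than `min_count` counts in every sample are removed
#' (keep a gene if it reaches `min_count` in at least one sample); counts
#' are CPM-normalized per sample; a gene is reported up (higher in
#' `group_a`) or down when the ratio of group means reaches `fold`
#' (inclusive). When both groups have replicates (>= 2 samples), a
#' two-sample test on log2(CPM + 1) with BH-adjusted p < `max_padj` is
#' additionally required.
#'
#' @param table an [expr_table()] of raw counts.
#' @param group_a,group_b group labels to compare.
#' @param fold linear fold-change threshold (default 2, inclusive).
#' @param min_count expression filter (default 50).
#' @param max_padj adjusted-p threshold in the replicated case (default
#'   0.1).
#' @param test two-sample test for the replicated case: `"t"` (Student's t
#'   on log2 CPM) or `"wilcox"`.
#' @return list: `up` and `down` data.frames (gene, log2fc, and p/padj with
#'   replicates), `n_tested` (genes surviving the count filter),
#'   `replicated` flag.
#' @export
de_fold_change <- function(table, group_a, group_b, fold = 2,
                           min_count = 50, max_padj = 0.1,
                           test = c("t", "wilcox")) {
  stopifnot(inherits(table, "expr_table"))
  test <- match.arg(test)
  if (!all(c(group_a, group_b) %in% table$groups))
    abort("groups '%s'/'%s' not both present", group_a, group_b)
  keep <- apply(table$values, 1, max) >= min_count
  vals <- table$values[keep, , drop = FALSE]
  cpm <- sweep(vals, 2, colSums(table$values), "/") * 1e6
  ia <- table$groups == group_a
  ib <- table$groups == group_b
  ma <- rowMeans(cpm[, ia, drop = FALSE])
  mb <- rowMeans(cpm[, ib, drop = FALSE])
  log2fc <- log2((ma + 1e-9) / (mb + 1e-9))
  up <- ma >= fold * mb
  down <- mb >= fold * ma
  replicated <- sum(ia) >= 2L && sum(ib) >= 2L
  p <- padj <- rep(NA_real_, nrow(cpm))
  if (replicated) {
    lg <- log2(cpm + 1)
    p <- vapply(seq_len(nrow(lg)), function(i) {
      xa <- lg[i, ia]; xb <- lg[i, ib]
      if (var(xa) == 0 && var(xb) == 0)
        return(if (mean(xa) == mean(xb)) 1 else 0)
      if (test == "t") t.test(xa, xb)$p.value
      else wilcox.test(xa, xb, exact = FALSE)$p.value
    }, numeric(1))
    padj <- bh_adjust(p)
    up <- up & padj < max_padj
    down <- down & padj < max_padj
  }
  mk <- function(sel) {
    df <- data.frame(gene = rownames(cpm)[sel], log2fc = log2fc[sel],
                     p = p[sel], padj = padj[sel],
                     stringsAsFactors = FALSE)
    df[order(-abs(df$log2fc)), , drop = FALSE]
  }
  list(up = mk(up), down = mk(down), n_tested = nrow(cpm),
       replicated = replicated)
}
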