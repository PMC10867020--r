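# Cell-cycle module scoring and phase assignment.
#
# Module score of a gene set in a cell = mean normalized expression of the
# set minus the mean of a control set.  Controls are drawn per signature
# gene from the same average-expression bin (genes binned by their mean
# normalized expression across cells), the standard binned-control scheme
# for expression-program scoring.  The draw is seeded and iterates genes in
# lexicographic order, so scores do not depend on input gene order.

#' Score a gene module against binned expression controls
#'
#' @param m a normalized [cell_matrix()] (run [log_normalize()] first).
#' @param sig a [gene_signature()] or character vector of genes; genes
#'   absent from the matrix are dropped with a warning.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes drawn per signature gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return numeric per-cell module score.
#' @export
module_score <- function(m, sig, n_bins = 24L, n_ctrl = 100L, seed = 0L) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$data)) abort("normalize before scoring (log_normalize)")
  genes <- if (inherits(sig, "gene_signature")) sig$genes else as.character(sig)
  present <- intersect(genes, colnames(m$data))
  if (length(present) < length(genes))
    warning(sprintf("%d signature genes absent from matrix, dropped",
                    length(genes) - length(present)))
  if (!length(present)) abort("signature empty after dropping absent genes")

  gene_order <- sort(colnames(m$data))     # canonical order for determinism
  avg <- Matrix::colSums(m$data)[gene_order] / nrow(m$data)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- gene_order
  ctrl <- character(0)
  with_seed(seed, {
    for (g in sort(present)) {
      pool <- gene_order[bins == bins[[g]]]
      ctrl <- c(ctrl, pool[sample.int(length(pool),
                                      min(n_ctrl, length(pool)))])
    }
  })
  ctrl <- unique(ctrl)
  sig_mean <- Matrix::rowSums(m$data[, present, drop = FALSE]) /
    length(present)
  ctrl_mean <- Matrix::rowSums(m$data[, ctrl, drop = FALSE]) / length(ctrl)
  as.numeric(sig_mean - ctrl_mean)
}

#' Score cell-cycle programs and call phases
#'
#' Computes S and G2M module scores ([module_score()]) and assigns a phase
#' per cell: S if the S score is positive and the larger of the two (ties
#' with a positive G2M score go to S), G2M if the G2M score is positive and
#' larger, otherwise G1.
#'
#' @param m a normalized [cell_matrix()].
#' @param s_genes,g2m_genes [gene_signature()]s (or gene vectors) of the
#'   S-phase and G2M programs.
#' @param n_bins,n_ctrl,seed control-draw parameters, see [module_score()].
#' @return The matrix with `s_score`, `g2m_score`, `phase` in `cell_meta`.
#' @export
score_cell_cycle <- function(m, s_genes, g2m_genes, n_bins = 24L,
                             n_ctrl = 100L, seed = 0L) {
  s <- module_score(m, s_genes, n_bins, n_ctrl, seed)
  g2m <- module_score(m, g2m_genes, n_bins, n_ctrl, seed + 1L)
  phase <- rep("G1", length(s))
  phase[s > 0 & s >= g2m] <- "S"
  phase[g2m > 0 & g2m > s] <- "G2M"
  m$cell_meta$s_score <- s
  m$cell_meta$g2m_score <- g2m
  m$cell_meta$phase <- phase
  m
}
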