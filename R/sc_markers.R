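# Cluster marker detection and cluster-level summaries.
#
# Marker test: Wilcoxon rank-sum of in-group vs all other cells on
# normalized values, vectorized over genes via a single global ranking per
# gene (the rank-sum of a group against the rest is a function of the
# pooled ranks).  P-values use the normal approximation with tie correction
# and continuity correction; BH adjustment is applied across the genes
# tested within each group.

#' Vectorized rank-sum test of a cell group vs the rest, all genes
#' @noRd
ranksum_group <- function(ranks, tie_term, in_group) {
  n <- nrow(ranks)
  n1 <- sum(in_group)
  n2 <- n - n1
  w <- colSums(ranks[in_group, , drop = FALSE]) - n1 * (n1 + 1) / 2
  sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1))))
  z <- w - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sigma
  p <- 2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE))
  pmin(p, 1)
}

#' Average log2 fold-change on the de-logged scale
#' @noRd
avg_log2fc <- function(data_lin, in_group, pseudocount) {
  mu_in <- colMeans(data_lin[in_group, , drop = FALSE])
  mu_out <- colMeans(data_lin[!in_group, , drop = FALSE])
  log2((mu_in + pseudocount) / (mu_out + pseudocount))
}

#' Marker detection for arbitrary cell groupings
#' @noRd
markers_by_group <- function(data, groups, min_log2fc, max_padj,
                             positive_only, pseudocount) {
  data <- as.matrix(data)
  n <- nrow(data)
  ranks <- apply(data, 2, rank)
  tie_term <- apply(data, 2, function(x) {
    t <- table(x); sum(t^3 - t)
  })
  data_lin <- expm1(data)
  out <- list()
  for (g in sort(unique(as.character(groups)))) {
    in_g <- as.character(groups) == g
    if (sum(in_g) < 2L) {
      warning(sprintf("group '%s' has fewer than 2 cells; skipped", g))
      next
    }
    p <- ranksum_group(ranks, tie_term, in_g)
    fc <- avg_log2fc(data_lin, in_g, pseudocount)
    padj <- bh_adjust(p)
    sel <- padj < max_padj &
      (if (positive_only) fc >= min_log2fc else abs(fc) >= min_log2fc)
    df <- data.frame(gene = colnames(data)[sel], log2fc = fc[sel],
                     p = p[sel], padj = padj[sel],
                     stringsAsFactors = FALSE)
    out[[g]] <- df[order(-df$log2fc), , drop = FALSE]
  }
  out
}

#' Find cluster marker genes
#'
#' Per cluster, rank-sum test of in-cluster vs all other cells on the
#' normalized values; genes with average log2 fold-change of at least
#' `min_log2fc` (default 0.25; use 0.5 with `positive_only` for the
#' stricter integrated LSC/blast marker list) and BH-adjusted p-value below
#' `max_padj` (default 0.1) are markers.
#'
#' @param m a clustered [cell_matrix()].
#' @param min_log2fc marker fold-change threshold (default 0.25).
#' @param max_padj BH-adjusted p-value threshold (default 0.1).
#' @param positive_only keep only positively enriched genes (default TRUE).
#' @param pseudocount pseudocount in the fold-change means (default 1).
#' @return list of `cluster_profile` objects (one per cluster): fields
#'   `cluster`, `markers` (data.frame gene/log2fc/p/padj), `mean_expr`,
#'   `class` (NA until classified), `order` (NA until ordered).
#' @export
find_cluster_markers <- function(m, min_log2fc = 0.25, max_padj = 0.1,
                                 positive_only = TRUE, pseudocount = 1) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$cell_meta$cluster)) abort("clusters not assigned")
  mk <- markers_by_group(m$data, m$cell_meta$cluster, min_log2fc,
                         max_padj, positive_only, pseudocount)
  lapply(names(mk), function(cl) {
    in_cl <- m$cell_meta$cluster == as.integer(cl)
    structure(list(cluster = as.integer(cl), markers = mk[[cl]],
                   mean_expr = colMeans(as.matrix(m$data[in_cl, ,
                                                         drop = FALSE])),
                   class = NA_character_, order = NA_integer_),
              class = "cluster_profile")
  })
}

#' Remove clusters lacking expression of a contamination marker gene
#'
#' Clusters in which fewer than `min_cells` cells have a nonzero raw count
#' of `gene` are treated as contaminating non-leukemic cells and removed
#' (default: fewer than 4 cells expressing RUNX1T1).
#'
#' @param m a clustered [cell_matrix()].
#' @param gene marker transcript of the malignant clone (default RUNX1T1).
#' @param min_cells minimum expressing cells for a cluster to be kept.
#' @return Filtered [cell_matrix()]; removed cluster ids in attribute
#'   `removed_clusters`.
#' @export
filter_contaminant_clusters <- function(m, gene = "RUNX1T1",
                                        min_cells = 4L) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$cell_meta$cluster)) abort("clusters not assigned")
  if (!gene %in% colnames(m$counts))
    abort("gene '%s' absent from the matrix", gene)
  expr <- as.numeric(m$counts[, gene]) > 0
  n_expr <- tapply(expr, m$cell_meta$cluster, sum)
  bad <- as.integer(names(n_expr))[n_expr < min_cells]
  out <- subset_cells(m, which(!m$cell_meta$cluster %in% bad))
  attr(out, "removed_clusters") <- bad
  out
}

#' Marker detection on a cell-cycle-phase subset
#'
#' Restricts marker detection to cells outside the excluded phases
#' (default S and G2M, i.e. G0/G1 cells only) and groups cells by an
#' arbitrary `cell_meta` column (typically the LSC/Blast class) instead of
#' cluster ids.
#'
#' @param m a [cell_matrix()] with phases and the grouping column set.
#' @param exclude_phases phases to drop (default `c("S", "G2M")`).
#' @param grouping `cell_meta` column to group by (default "class").
#' @param ... passed to the marker engine (thresholds as in
#'   [find_cluster_markers()]).
#' @param min_log2fc,max_padj,positive_only,pseudocount see
#'   [find_cluster_markers()].
#' @return named list of marker data.frames, one per group label.
#' @export
phase_subset_markers <- function(m, exclude_phases = c("S", "G2M"),
                                 grouping = "class", min_log2fc = 0.25,
                                 max_padj = 0.1, positive_only = TRUE,
                                 pseudocount = 1) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$cell_meta$phase)) abort("phases not assigned")
  if (is.null(m$cell_meta[[grouping]]))
    abort("grouping column '%s' not set", grouping)
  keep <- !(m$cell_meta$phase %in% exclude_phases)
  if (!any(keep)) abort("phase subset is empty")
  sub <- subset_cells(m, which(keep))
  markers_by_group(sub$data, sub$cell_meta[[grouping]], min_log2fc,
                   max_padj, positive_only, pseudocount)
}

#' Order clusters along the LSC-to-blast axis
#'
#' Pseudotime stand-in: clusters are ordered by ascending mean blast-
#' signature module score, so the most LSC-like cluster comes first (the
#' root of the differentiation axis).
#'
#' @param m a clustered, normalized [cell_matrix()].
#' @param blast_sig blast [gene_signature()].
#' @param seed control-draw seed for the module score.
#' @return integer vector of cluster ids, most LSC-like first.
#' @export
order_clusters <- function(m, blast_sig, seed = 0L) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$cell_meta$cluster)) abort("clusters not assigned")
  sc <- module_score(m, blast_sig, seed = seed)
  mean_sc <- tapply(sc, m$cell_meta$cluster, mean)
  as.integer(names(sort(mean_sc)))
}

#' Z-score matrix of per-cluster mean signature expression
#'
#' Per signature gene, the per-cluster mean normalized expression is
#' transformed to a Z-score across clusters (sample sd, n-1; constant rows
#' map to 0). Columns follow the supplied cluster ordering; rows are
#' grouped by the cluster in which they peak (in column order) and sorted
#' by descending Z within that group.
#'
#' @param m a clustered, normalized [cell_matrix()].
#' @param sig a [gene_signature()]; genes absent from the matrix are
#'   dropped with a warning.
#' @param ordering cluster ids in display order (default:
#'   [order_clusters()] output or sorted ids).
#' @return genes x clusters Z matrix.
#' @export
cluster_signature_zscore <- function(m, sig, ordering = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$cell_meta$cluster)) abort("clusters not assigned")
  genes <- intersect(sig$genes, colnames(m$data))
  if (length(genes) < length(sig$genes))
    warning(sprintf("%d signature genes absent, dropped",
                    length(sig$genes) - length(genes)))
  cl <- sort(unique(m$cell_meta$cluster))
  if (is.null(ordering)) ordering <- cl
  means <- vapply(cl, function(c1)
    colMeans(as.matrix(m$data[m$cell_meta$cluster == c1, genes,
                              drop = FALSE])),
    numeric(length(genes)))
  if (length(genes) == 1L) means <- matrix(means, nrow = 1)
  dimnames(means) <- list(genes, cl)
  z <- t(apply(means, 1, function(r) {
    s <- sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(means)
  z <- z[, as.character(ordering), drop = FALSE]
  peak <- apply(z, 1, which.max)
  z[order(peak, -apply(z, 1, max)), , drop = FALSE]
}
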