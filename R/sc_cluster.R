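# Cell-cycle regression, scaling, PCA and graph clustering.
#
# To keep results independent of input cell order, the graph/cluster stage
# operates on cells in lexicographic barcode order internally and maps the
# partition back to the caller's order.

#' Regress out cell-cycle scores, scale, and cluster cells
#'
#' Per gene, normalized values are replaced by residuals of an ordinary
#' least-squares fit on (intercept, S score, G2M score); residuals are
#' z-scaled per gene (clipped at +/-10); PCA is run on the scaled matrix
#' and a shared-nearest-neighbour graph (Jaccard weights over `k_nn`
#' Euclidean neighbours in PC space, edges below `prune` dropped) is
#' partitioned by modularity-based community detection (Louvain) at the
#' given resolution. Cluster ids are renumbered by size, descending.
#'
#' @param m a [cell_matrix()] with cycle scores ([score_cell_cycle()]).
#' @param resolution modularity resolution (default 0.8).
#' @param n_pcs number of principal components (default 10).
#' @param k_nn neighbours for the SNN graph (default 20).
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @param batch optional `cell_meta` column name; gene means are centred
#'   within each batch after scaling (a deliberately simple stand-in for
#'   anchor-based dataset integration, flagged in the result metadata).
#' @param seed seed for the community detection.
#' @return The matrix with `$scaled`, `$pca` and a `cluster` column in
#'   `cell_meta` (integer, 1 = largest).
#' @export
regress_scale_cluster <- function(m, resolution = 0.8, n_pcs = 10L,
                                  k_nn = 20L, prune = 1 / 15,
                                  batch = NULL, seed = 0L) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$cell_meta$s_score)) abort("run score_cell_cycle first")
  n <- n_cells(m)
  if (n <= n_pcs) abort("fewer cells (%d) than principal components", n)

  y <- as.matrix(m$data)
  x <- cbind(1, m$cell_meta$s_score, m$cell_meta$g2m_score)
  beta <- solve(crossprod(x), crossprod(x, y))
  res <- y - x %*% beta
  sds <- apply(res, 2, sd)
  # numerically-zero residual genes (e.g. perfectly fitted by the scores)
  # must not be blown up by the z-scale
  sds[sds < 1e-10] <- Inf
  scl <- sweep(res, 2, sds, "/")
  scl[scl > 10] <- 10; scl[scl < -10] <- -10
  if (!is.null(batch)) {
    b <- m$cell_meta[[batch]]
    for (bv in unique(b)) {
      i <- which(b == bv)
      scl[i, ] <- sweep(scl[i, , drop = FALSE], 2,
                        colMeans(scl[i, , drop = FALSE]))
    }
    attr(m, "integration") <- "per-batch gene-mean centering"
  }
  m$scaled <- scl

  ord <- order(rownames(m$counts))          # canonical cell order
  pc_ord <- prcomp(scl[ord, , drop = FALSE], center = TRUE,
                   scale. = FALSE, rank. = n_pcs)$x
  cl_ord <- snn_louvain(pc_ord, k_nn = k_nn, prune = prune,
                        resolution = resolution, seed = seed)
  cl <- integer(n)
  cl[ord] <- cl_ord
  pca <- matrix(0, n, ncol(pc_ord))
  pca[ord, ] <- pc_ord
  rownames(pca) <- rownames(m$counts)
  m$pca <- pca
  # renumber by cluster size (desc); ties by smallest canonical member
  sizes <- table(cl_ord)
  first <- tapply(seq_len(length(cl_ord)), cl_ord, min)
  ids <- as.integer(names(sizes))
  by_rank <- order(-as.numeric(sizes), as.numeric(first))
  new_of <- integer(max(ids))
  new_of[ids[by_rank]] <- seq_along(ids)
  m$cell_meta$cluster <- new_of[cl]
  m
}

#' SNN graph + Louvain partition of an embedding
#' @noRd
snn_louvain <- function(emb, k_nn, prune, resolution, seed) {
  n <- nrow(emb)
  k <- min(k_nn, n)
  d <- as.matrix(dist(emb))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))  # includes self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1,
                              dims = c(n, n))
  jac <- as(Matrix::tcrossprod(adj), "CsparseMatrix")
  jac@x <- jac@x / (2 * k - jac@x)     # Jaccard: |A&B| / |A|B| union
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- with_seed(seed,
                  igraph::cluster_louvain(g, resolution = resolution))
  igraph::membership(cl)
}
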