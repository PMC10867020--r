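# Single-cell QC and normalization.

#' Per-cell QC statistics
#'
#' Adds `n_genes_detected` (genes with count > 0), `total_umi` and
#' `mito_fraction` (UMIs on "MT-"-flagged genes / total) to `cell_meta`.
#'
#' @param m a [cell_matrix()].
#' @return The matrix with QC columns filled in.
#' @export
compute_qc_stats <- function(m) {
  stopifnot(inherits(m, "cell_matrix"))
  cnt <- m$counts
  m$cell_meta$n_genes_detected <- as.integer(Matrix::rowSums(cnt > 0))
  tot <- Matrix::rowSums(cnt)
  m$cell_meta$total_umi <- as.numeric(tot)
  mito <- m$gene_meta$mito
  mito_umi <- if (any(mito))
    Matrix::rowSums(cnt[, mito, drop = FALSE]) else 0
  m$cell_meta$mito_fraction <- ifelse(tot > 0,
                                      as.numeric(mito_umi) / as.numeric(tot),
                                      0)
  m
}

#' Filter low-quality cells
#'
#' Retains cells with detected-gene count in `[min_genes, max_genes]`
#' (inclusive bounds) and mitochondrial UMI fraction `<= max_mito`.
#' Removal counts are reported via `message()` and recorded in the result's
#' `qc_log` attribute.
#'
#' @param m a [cell_matrix()].
#' @param min_genes,max_genes detected-gene bounds (defaults 200 and 5000;
#'   cells with fewer than 200 or more than 5000 genes are removed).
#' @param max_mito maximum mitochondrial fraction (default 0.15).
#' @return Filtered [cell_matrix()].
#' @export
qc_filter <- function(m, min_genes = 200L, max_genes = 5000L,
                      max_mito = 0.15) {
  check_prop(max_mito, "max_mito")
  m <- compute_qc_stats(m)
  ng <- m$cell_meta$n_genes_detected
  mf <- m$cell_meta$mito_fraction
  keep <- ng >= min_genes & ng <= max_genes & mf <= max_mito
  log <- c(total = length(keep),
           low_genes = sum(ng < min_genes),
           high_genes = sum(ng > max_genes),
           high_mito = sum(mf > max_mito & ng >= min_genes & ng <= max_genes),
           kept = sum(keep))
  message(sprintf("qc_filter: kept %d/%d cells (%d low-gene, %d high-gene, %d high-mito)",
                  log[["kept"]], log[["total"]], log[["low_genes"]],
                  log[["high_genes"]], log[["high_mito"]]))
  if (!any(keep)) abort("qc_filter removed every cell")
  out <- subset_cells(m, which(keep))
  attr(out, "qc_log") <- log
  out
}

#' Log-normalize UMI counts
#'
#' Per cell: `x -> ln(1 + scale * x / total_umi)`, the standard
#' log-normalization with scale factor 10,000.
#'
#' @param m a QC-filtered [cell_matrix()].
#' @param scale library-size scale factor (default 1e4).
#' @return The matrix with the normalized sparse matrix in `$data`.
#' @export
log_normalize <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "cell_matrix"))
  tot <- Matrix::rowSums(m$counts)
  if (any(tot == 0)) abort("cell with zero total UMIs; run qc_filter first")
  d <- m$counts
  # cells are rows; @i holds each entry's 0-based row index
  d@x <- log1p(scale * d@x / tot[d@i + 1L])
  m$data <- d
  m
}
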