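# Core data containers.
#
# The package keeps containers deliberately light: plain S3 lists wrapping
# base matrices (bulk), Matrix sparse matrices (single cell) and data.frames
# (genomic intervals).  Interval arithmetic converts to GRanges internally.

#' Construct a bulk expression table
#'
#' A genes x samples matrix of non-negative expression values (FPKM or raw
#' counts) with one group label per sample and an optional protein-coding
#' flag per gene.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Values must be >= 0.
#' @param groups character/factor of length `ncol(values)`; the biological
#'   group of each sample (e.g. "LSC", "Blast", "t821", "PBSC").
#' @param coding logical per-gene protein-coding flag (default all `TRUE`).
#' @param state one of `"raw"` (FPKM or counts) or `"lognorm"`
#'   (upper-quartile normalized, log2(x + pseudocount)).
#' @return An object of class `expr_table`.
#' @export
expr_table <- function(values, groups, coding = NULL, state = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values))) abort("`values` needs gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    abort("duplicate gene ids in expression table")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    abort("`groups` must label every sample (%d labels for %d samples)",
          length(groups), ncol(values))
  if (any(is.na(groups))) abort("every sample needs a group label")
  if (is.null(coding)) coding <- rep(TRUE, nrow(values))
  if (length(coding) != nrow(values))
    abort("`coding` must flag every gene")
  if (state == "raw" && any(values < 0))
    abort("raw expression values must be non-negative")
  structure(
    list(values = values, groups = groups,
         coding = as.logical(coding), state = state),
    class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expr_table: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  cat("groups:", paste(sprintf("%s(%d)", names(table(x$groups)),
                               table(x$groups)), collapse = " "), "\n")
  invisible(x)
}

#' Construct a directed gene signature
#'
#' A named gene set with per-gene log2 fold-changes, as produced by the bulk
#' signature derivations and consumed by GSEA classification and module
#' scoring.
#'
#' @param name signature label, e.g. "LSC" or "t821-specific".
#' @param genes character vector of unique gene ids.
#' @param log2fc numeric per-gene log2 fold-change (same length as `genes`);
#'   defaults to 0.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, log2fc = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) abort("signature genes must be unique")
  if (is.null(log2fc)) log2fc <- rep(0, length(genes))
  if (length(log2fc) != length(genes))
    abort("`log2fc` must match `genes` in length")
  if (length(log2fc) && any(!is.finite(log2fc)))
    abort("signature log2 fold-changes must be finite")
  structure(list(name = name, genes = genes,
                 log2fc = setNames(as.numeric(log2fc), genes)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Construct a single-cell UMI count container
#'
#' Wraps a sparse cells x genes UMI count matrix with per-cell and per-gene
#' metadata. Downstream steps (QC, normalization, cell-cycle scoring,
#' clustering) add columns to `cell_meta` and slots for derived matrices.
#'
#' @param counts sparse (or dense) cells x genes matrix of non-negative
#'   integer UMI counts; rownames = cell barcodes, colnames = gene names.
#' @param cell_meta data.frame of per-cell annotations (one row per cell);
#'   created empty if omitted. Typical columns: `patient`, `sorted_label`.
#' @param gene_meta data.frame of per-gene annotations; a logical `mito`
#'   column is derived from the "MT-" name prefix if absent.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) == 0L) abort("empty cell matrix: no cells")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell_%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) abort("`counts` needs gene names as colnames")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    abort("UMI counts must be non-negative integers")
  if (is.null(cell_meta))
    cell_meta <- data.frame(row.names = rownames(counts))
  if (nrow(cell_meta) != nrow(counts)) abort("cell_meta/counts row mismatch")
  rownames(cell_meta) <- rownames(counts)
  if (is.null(gene_meta))
    gene_meta <- data.frame(row.names = colnames(counts))
  if (is.null(gene_meta$mito))
    gene_meta$mito <- startsWith(colnames(counts), "MT-")
  rownames(gene_meta) <- colnames(counts)
  structure(list(counts = counts, data = NULL, scaled = NULL, pca = NULL,
                 cell_meta = cell_meta, gene_meta = gene_meta),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d genes (%s normalized%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$data)) "not" else "log-",
              if ("cluster" %in% names(x$cell_meta)) ", clustered" else ""))
  invisible(x)
}

#' Number of cells / genes in a cell_matrix
#' @param x a `cell_matrix`.
#' @return integer count.
#' @export
n_cells <- function(x) nrow(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x$counts)

#' Subset a cell_matrix by cell index
#' @noRd
subset_cells <- function(m, keep) {
  m$counts <- m$counts[keep, , drop = FALSE]
  if (!is.null(m$data)) m$data <- m$data[keep, , drop = FALSE]
  if (!is.null(m$scaled)) m$scaled <- m$scaled[keep, , drop = FALSE]
  if (!is.null(m$pca)) m$pca <- m$pca[keep, , drop = FALSE]
  m$cell_meta <- m$cell_meta[keep, , drop = FALSE]
  m
}

#' Construct a peak collection
#'
#' Genomic intervals in BED dialect: 0-based half-open `[start, end)` with a
#' single-bp summit (absolute coordinate, `start <= summit < end`). Rows are
#' kept sorted by (chrom, start).
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param summit absolute summit position; defaults to the interval midpoint.
#' @param score numeric per-peak score (default 0).
#' @param name peak ids (default "peak_1" ...).
#' @return data.frame of class `peak_set` with columns
#'   chrom/start/end/name/score/summit.
#' @export
peak_set <- function(chrom, start, end, summit = NULL, score = NULL,
                     name = NULL) {
  n <- length(start)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) abort("malformed interval: start >= end")
  if (is.null(summit)) summit <- start + (end - start) %/% 2L
  summit <- as.integer(summit)
  if (any(summit < start | summit >= end))
    abort("summit outside its interval")
  if (is.null(score)) score <- rep(0, n)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), score = as.numeric(score),
                   summit = summit, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Convert a peak_set to GRanges (internal; 1-based closed)
#' @noRd
peaks_to_gr <- function(p) {
  GenomicRanges::GRanges(p$chrom,
                         IRanges::IRanges(p$start + 1L, p$end),
                         summit = p$summit, score = p$score, name = p$name)
}

#' Construct a tag-density matrix over peak windows
#' @noRd
tag_matrix <- function(values, peaks, state, half_width) {
  structure(list(values = values, peaks = peaks, state = state,
                 half_width = half_width),
            class = "tag_matrix")
}
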