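# Synthetic single-cell UMI generator.

#' Generate synthetic single-cell UMI counts with planted populations
#'
#' Draws negative-binomial UMI counts over the shared gene universe. Each
#' population up-shifts its marker program (and any secondary programs) by
#' the configured log2 effect; cells are assigned a true cell-cycle phase
#' from the population's G1/S/G2M fractions, with the planted S or G2M
#' program up-shifted by `cycle_effect` in cells of that phase.
#' Mitochondrial ("MT-") UMIs are added so each cell's mitochondrial
#' fraction matches a draw from `mito_fraction_range`.
#'
#' @param cfg a [sim_config()].
#' @return A [cell_matrix()] whose `cell_meta` carries the ground truth
#'   (`true_pop`, `true_phase`, `sorted_label`, `patient`) and whose
#'   attribute `ground_truth` records marker programs and the seed.
#' @export
gen_sc_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cells_per_population <= 0L)
    abort("n_cells_per_population must be positive: empty matrix requested")
  pops <- cfg$populations
  if (!all(c("LSC", "Blast") %in% names(pops)))
    abort("populations must include at least 'LSC' and 'Blast'")
  for (p in pops) if (!is.null(p$effect) && p$effect < 0)
    abort("marker effects must be non-negative")
  genes <- sim_gene_names(cfg)
  mito_idx <- which(startsWith(genes, "MT-"))
  nonmito <- setdiff(seq_len(cfg$n_genes), mito_idx)
  n_per <- cfg$n_cells_per_population
  n_cells <- n_per * length(pops)

  with_seed(cfg$seed + 202L, {
    base_mu <- rlnorm(cfg$n_genes, meanlog = log(2), sdlog = 0.8)
    if ("RUNX1T1" %in% genes) base_mu[genes == "RUNX1T1"] <- 5  # fusion
    counts <- matrix(0L, n_cells, cfg$n_genes)
    true_pop <- character(n_cells)
    true_phase <- character(n_cells)
    row <- 0L
    for (pn in names(pops)) {
      p <- pops[[pn]]
      mu_pop <- base_mu
      mu_pop[p$markers] <- mu_pop[p$markers] * 2^p$effect
      for (ex in p$extra_markers %||% list())
        mu_pop[ex$idx] <- mu_pop[ex$idx] * 2^ex$effect
      phases <- sample(names(p$cycle_fractions), n_per, replace = TRUE,
                       prob = p$cycle_fractions)
      for (i in seq_len(n_per)) {
        mu <- mu_pop * rlnorm(1, 0, cfg$depth_sdlog)
        if (phases[i] == "S")
          mu[cfg$s_genes] <- mu[cfg$s_genes] * 2^cfg$cycle_effect
        if (phases[i] == "G2M")
          mu[cfg$g2m_genes] <- mu[cfg$g2m_genes] * 2^cfg$cycle_effect
        x <- rnbinom(length(nonmito), mu = mu[nonmito],
                     size = cfg$nb_dispersion)
        counts[row + i, nonmito] <- x
        if (length(mito_idx)) {
          f <- runif(1, cfg$mito_fraction_range[1], cfg$mito_fraction_range[2])
          mt_total <- round(f / (1 - f) * sum(x))
          if (mt_total > 0)
            counts[row + i, mito_idx] <-
              as.integer(rmultinom(1, mt_total,
                                   prob = rep(1, length(mito_idx))))
        }
      }
      true_pop[row + seq_len(n_per)] <- pn
      true_phase[row + seq_len(n_per)] <- phases
      row <- row + n_per
    }
  })
  dimnames(counts) <- list(sprintf("cell_%04d", seq_len(n_cells)), genes)
  sorted <- ifelse(true_pop %in% c("LSC", "Blast"), true_pop, "unknown")
  meta <- data.frame(patient = "sim1", sorted_label = sorted,
                     true_pop = true_pop, true_phase = true_phase,
                     row.names = rownames(counts))
  m <- cell_matrix(Matrix::Matrix(counts, sparse = TRUE), cell_meta = meta)
  truth <- list(
    seed = cfg$seed,
    markers = lapply(pops, function(p) genes[p$markers]),
    s_genes = genes[cfg$s_genes], g2m_genes = genes[cfg$g2m_genes])
  attr(m, "ground_truth") <- truth
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic cell matrix as MTX + TSV + metadata + truth JSON
#'
#' Layout follows the 10x convention: `matrix.mtx` (genes x cells),
#' `barcodes.tsv`, `features.tsv`, plus `cell_meta.tsv` and
#' `sc_truth.json`.
#'
#' @param m a [cell_matrix()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_sim_sc <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "features.tsv"))
  write.table(cbind(barcode = rownames(m$cell_meta), m$cell_meta),
              file.path(dir, "cell_meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gt <- attr(m, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, file.path(dir, "sc_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cell matrix written by [write_sim_sc()]
#'
#' @param dir directory with `matrix.mtx`, `barcodes.tsv`, `features.tsv`.
#' @return A [cell_matrix()].
#' @export
read_sim_sc <- function(dir) {
  mm <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(mm) <- readLines(file.path(dir, "barcodes.tsv"))
  colnames(mm) <- readLines(file.path(dir, "features.tsv"))
  meta_path <- file.path(dir, "cell_meta.tsv")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- read.table(meta_path, header = TRUE, sep = "\t",
                       row.names = 1, check.names = FALSE)
  }
  m <- cell_matrix(mm, cell_meta = meta)
  gt_path <- file.path(dir, "sc_truth.json")
  if (file.exists(gt_path))
    attr(m, "ground_truth") <- jsonlite::read_json(gt_path,
                                                   simplifyVector = TRUE)
  m
}
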