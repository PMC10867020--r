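# End-to-end workflow drivers tying the modules together.

#' Run the full single-cell classification workflow on synthetic data
#'
#' Generates a matched synthetic cohort (bulk FPKM + single-cell UMIs) from
#' one config, derives the bulk blast-vs-LSC ranking, runs the single-cell
#' pipeline (QC, normalization, cell-cycle scoring and regression,
#' clustering, contamination filter, marker detection) and classifies every
#' cluster by preranked GSEA.
#'
#' @param seed integer seed driving the whole run.
#' @param cfg optional [sim_config()]; defaults to `sim_config(seed)`.
#' @param resolution,n_pcs clustering parameters (defaults 0.8 / 10).
#' @return list: `matrix` (the processed [cell_matrix()]), `profiles`
#'   (classified cluster profiles), `summary` (data.frame with cluster id,
#'   size, majority true population, NES, adjusted p, class).
#' @export
run_sc_classification <- function(seed, cfg = NULL, resolution = 0.8,
                                  n_pcs = 10L) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed)
  bulk <- gen_bulk_expression(cfg)
  ranking <- rank_genes(bulk, "Blast", "LSC")
  m <- gen_sc_counts(cfg)
  gt <- attr(m, "ground_truth")
  m <- suppressMessages(qc_filter(m))
  m <- log_normalize(m)
  m <- score_cell_cycle(m, gt$s_genes, gt$g2m_genes, seed = seed + 1L)
  m <- regress_scale_cluster(m, resolution = resolution, n_pcs = n_pcs,
                             seed = seed + 2L)
  m <- filter_contaminant_clusters(m)
  profiles <- find_cluster_markers(m)
  profiles <- classify_clusters(profiles, ranking = ranking,
                                seed = seed + 3L)
  m <- assign_cell_classes(m, profiles)
  summary <- do.call(rbind, lapply(profiles, function(p) {
    in_cl <- m$cell_meta$cluster == p$cluster
    data.frame(cluster = p$cluster, n_cells = sum(in_cl),
               true_pop = names(which.max(table(
                 m$cell_meta$true_pop[in_cl]))),
               nes = p$nes, padj = p$padj, class = p$class,
               stringsAsFactors = FALSE)
  }))
  list(matrix = m, profiles = profiles, summary = summary)
}

#' Score classification recovery against the planted populations
#'
#' A run recovers the planted structure when every majority-LSC cluster is
#' classed LSC, every majority-Blast cluster is classed Blast, and no
#' majority-transition cluster is pulled to either pole.
#'
#' @param summary the `summary` component of [run_sc_classification()].
#' @return list of logicals: `lsc_ok`, `blast_ok`, `transition_ok`,
#'   `all_ok`.
#' @export
score_classification_recovery <- function(summary) {
  lsc <- summary$class[summary$true_pop == "LSC"]
  blast <- summary$class[summary$true_pop == "Blast"]
  trans <- summary$class[!summary$true_pop %in% c("LSC", "Blast")]
  out <- list(lsc_ok = length(lsc) > 0 && all(lsc == "LSC"),
              blast_ok = length(blast) > 0 && all(blast == "Blast"),
              transition_ok = all(trans == "LSC/Blast"))
  out$all_ok <- out$lsc_ok && out$blast_ok && out$transition_ok
  out
}
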