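#!/usr/bin/env Rscript
# Stage 3: single-cell pipeline and LSC/blast cluster classification.
#
# QC (200-5000 detected genes, <=15% mitochondrial UMIs), log-normalize,
# cell-cycle module scores with phase calls, OLS cycle regression +
# z-scale, PCA, SNN/Louvain clustering at resolution 0.8, RUNX1T1
# contamination filter, rank-sum cluster markers (log2FC >= 0.25, BH
# p < 0.1), preranked GSEA classification against the bulk ranking
# (|NES| > 1, BH p < 0.05), pseudotime-stand-in cluster ordering, and the
# t(8;21)-signature Z-score matrix plus the G0/G1-restricted marker lists.

suppressPackageStartupMessages(library(stemsig))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
datadir <- "results/data"
outdir <- "results/single_cell"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

m <- read_sim_sc(datadir)
gt <- attr(m, "ground_truth")
m <- qc_filter(m)
m <- log_normalize(m)
m <- score_cell_cycle(m, gt$s_genes, gt$g2m_genes, seed = seed + 1L)
cat(sprintf("phases: %s\n",
            paste(names(table(m$cell_meta$phase)),
                  table(m$cell_meta$phase), collapse = " ")))
m <- regress_scale_cluster(m, resolution = 0.8, seed = seed + 2L)
m <- filter_contaminant_clusters(m)
cat(sprintf("%d clusters after contamination filter\n",
            length(unique(m$cell_meta$cluster))))

profiles <- find_cluster_markers(m)
ranking <- local({
  df <- read.table("results/signatures/blast_vs_lsc_ranking.tsv",
                   header = TRUE, sep = "\t")
  setNames(df$log2fc, df$gene)
})
profiles <- classify_clusters(profiles, ranking = ranking,
                              seed = seed + 3L)
m <- assign_cell_classes(m, profiles)

summary <- do.call(rbind, lapply(profiles, function(p) {
  in_cl <- m$cell_meta$cluster == p$cluster
  data.frame(cluster = p$cluster, n_cells = sum(in_cl),
             true_pop = names(which.max(table(
               m$cell_meta$true_pop[in_cl]))),
             n_markers = nrow(p$markers), es = p$es, nes = p$nes,
             p = p$p, padj = p$padj, class = p$class)
}))
write.csv(summary, file.path(outdir, "cluster_classification.csv"),
          row.names = FALSE)
print(summary, row.names = FALSE)

markers <- do.call(rbind, lapply(profiles, function(p)
  cbind(cluster = p$cluster, p$markers)))
write.csv(markers, file.path(outdir, "cluster_markers.csv"),
          row.names = FALSE)

# order clusters along the LSC -> blast axis and compute the
# subtype-signature Z-score heatmap matrix
blast_sig <- read_signature("results/signatures/blast_signature.tsv")
ord <- order_clusters(m, blast_sig, seed = seed + 4L)
cat("cluster order (LSC-like first):", paste(ord, collapse = " "), "\n")
t821 <- read_signature("results/signatures/t821_specific.tsv")
z <- suppressWarnings(cluster_signature_zscore(m, t821, ordering = ord))
write.csv(z, file.path(outdir, "t821_zscore_matrix.csv"))

# G0/G1-restricted markers by class
g01 <- phase_subset_markers(m, exclude_phases = c("S", "G2M"),
                            grouping = "class")
for (cl in names(g01))
  write.csv(g01[[cl]],
            file.path(outdir, sprintf("g0g1_markers_%s.csv",
                                      gsub("/", "_", cl))),
            row.names = FALSE)
cat(sprintf("G0/G1 marker lists: %s\n",
            paste(names(g01), vapply(g01, nrow, integer(1)),
                  sep = "=", collapse = " ")))

write.table(cbind(barcode = rownames(m$cell_meta), m$cell_meta),
            file.path(outdir, "cell_metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
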