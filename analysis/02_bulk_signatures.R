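#!/usr/bin/env Rscript
# Stage 2: derive the bulk expression signatures.
#
# LSC vs blast: protein-coding genes above the FPKM floor in either sorted
# population, split by which population's upper-quartile-normalized mean is
# higher.  Subtype-specific genes: at least 2-fold above EVERY other
# subtype's mean (all-versus-each).  Also writes the blast-minus-LSC
# ranking used by the single-cell cluster classifier.

suppressPackageStartupMessages(library(stemsig))

datadir <- "results/data"
outdir <- "results/signatures"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

bulk <- read_sim_bulk(datadir)
sig <- derive_lsc_blast_signature(bulk)
write_signature(sig$lsc, file.path(outdir, "lsc_signature.tsv"))
write_signature(sig$blast, file.path(outdir, "blast_signature.tsv"))
gt <- attr(bulk, "ground_truth")
cat(sprintf("LSC signature: %d genes (%d/%d planted recovered)\n",
            length(sig$lsc$genes),
            length(intersect(sig$lsc$genes, gt$planted$LSC)),
            length(gt$planted$LSC)))
cat(sprintf("blast signature: %d genes (%d/%d planted recovered)\n",
            length(sig$blast$genes),
            length(intersect(sig$blast$genes, gt$planted$Blast)),
            length(gt$planted$Blast)))

ranking <- rank_genes(bulk, "Blast", "LSC")
write.table(data.frame(gene = names(ranking), log2fc = ranking),
            file.path(outdir, "blast_vs_lsc_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sub_tab <- read_sim_bulk(file.path(datadir, "subtype_panel"))
sub <- derive_subtype_specific_genes(sub_tab, "t821", fold = 2)
write_signature(sub, file.path(outdir, "t821_specific.tsv"))
sub_gt <- attr(sub_tab, "ground_truth")$planted$t821
cat(sprintf("t(8;21)-specific: %d genes (%d/%d planted recovered)\n",
            length(sub$genes), length(intersect(sub$genes, sub_gt)),
            length(sub_gt)))
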