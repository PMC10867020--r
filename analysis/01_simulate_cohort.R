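#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort every later stage consumes.
#
# One seeded configuration produces matched inputs that emulate the study
# design: sorted LSC/blast bulk FPKM tables, a three-population single-cell
# UMI matrix (quiescent LSC, transition, proliferating blasts), a two-set
# chromatin landscape with planted motif content and accessibility
# fold-changes, and a two-population CyTOF panel.

suppressPackageStartupMessages(library(stemsig))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)

bulk <- gen_bulk_expression(cfg)
write_sim_bulk(bulk, outdir)
cat(sprintf("bulk: %d genes x %d samples; planted %s\n",
            nrow(bulk$values), ncol(bulk$values),
            paste(names(attr(bulk, "ground_truth")$planted),
                  collapse = "/")))

sc <- gen_sc_counts(cfg)
write_sim_sc(sc, outdir)
cat(sprintf("single-cell: %d cells x %d genes (%s)\n", n_cells(sc),
            n_genes(sc),
            paste(names(table(sc$cell_meta$true_pop)), collapse = "/")))

land <- gen_peak_landscape(cfg)
write_sim_peaks(land, outdir)
cat(sprintf("chromatin: %d-bp genome, %s peaks, %d planted motif instances\n",
            nchar(land$genome[["chrS"]]),
            paste(vapply(land$peaks, nrow, integer(1)), collapse = "+"),
            nrow(land$insertions)))
write_motifs(cfg$peaks$motifs, file.path(outdir, "motifs.txt"))

cyt <- gen_cytof_table(cfg)
write_sim_cytof(cyt, outdir)
cat(sprintf("cytof: %d events x %d markers\n", nrow(cyt$counts),
            ncol(cyt$counts)))

# a subtype panel for the t(8;21)-specific gene derivation
cfg_sub <- sim_config(seed = seed + 1L, bulk = list(
  groups = c(t821 = 2L, inv16 = 2L, NPM1 = 2L, PBSC = 2L),
  planted = list(list(group = "t821", idx = 1:88, fold = 4)),
  noise_sdlog = 0.15))
sub <- gen_bulk_expression(cfg_sub)
write_sim_bulk(sub, file.path(outdir, "subtype_panel"))
cat(sprintf("subtype panel: groups %s\n",
            paste(unique(sub$groups), collapse = "/")))
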