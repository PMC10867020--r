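#!/usr/bin/env Rscript
# Stage 5: mass-cytometry population statistics.
#
# log2(x+1)-transform ion counts, summarise per-population marker means,
# compare blasts against LSCs with two-sided t-tests banded at
# p <= 1e-3 / 1e-5 / 1e-10, and write the population fold heatmap.

suppressPackageStartupMessages(library(stemsig))

datadir <- "results/data"
outdir <- "results/cytof"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

df <- read.csv(file.path(datadir, "cytof_ions.csv"), check.names = FALSE)
t <- structure(list(
  counts = as.matrix(df[, setdiff(names(df),
                                  c("event", "population", "patient"))]),
  population = df$population, patient = df$patient),
  class = "ion_table")

sm <- transform_and_summarize(t)
write.csv(sm$log2_means, file.path(outdir, "population_log2_means.csv"))

cmp <- compare_populations(t, "Blast", "LSC")
write.csv(cmp, file.path(outdir, "blast_vs_lsc.csv"), row.names = FALSE)
cat("Blast vs LSC:\n")
print(cmp, row.names = FALSE)

fh <- population_fold_heatmap(t)
write.csv(fh, file.path(outdir, "population_fold_heatmap.csv"))
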