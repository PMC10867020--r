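#!/usr/bin/env Rscript
# Stage 4: differential chromatin accessibility and motif enrichment.
#
# Builds the peak union, quantifies 400-bp summit windows as
# log2(CPM + 0.1), calls 2-fold differential sites, ranks density matrices
# by fold change, computes normalized average profiles and their
# fold-change summary, the Spearman binding-correlation heatmap, the Eq.-1
# style motif enrichment scores over the differential peak sets, and a
# motif-to-summit spacing profile.  Peaks are finally assigned to genes via
# a (synthetic) Hi-C association table with nearest-TSS fallback.

suppressPackageStartupMessages(library(stemsig))

datadir <- "results/data"
outdir <- "results/chromatin"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome(file.path(datadir, "genome.fa"))
peaks <- list(A = read_peaks(file.path(datadir, "peaks_A.bed")),
              B = read_peaks(file.path(datadir, "peaks_B.bed")))
glen <- c(chrS = nchar(genome[["chrS"]]))
coverage <- list(
  condA = read_bedgraph(file.path(datadir, "coverage_condA.bedGraph"), glen),
  condB = read_bedgraph(file.path(datadir, "coverage_condB.bedGraph"), glen))
motifs <- read_motifs(file.path(datadir, "motifs.txt"))

un <- merge_peak_union(peaks)
cat(sprintf("peak union: %d sites\n", nrow(un)))
tm <- quantify_windows(un, coverage, half_width = 200,
                       normalize = "log2cpm")
write.csv(tm$values, file.path(outdir, "tag_matrix_log2cpm.csv"))

ds <- differential_sites(tm, "condA", "condB", fold = 2)
write_bed(ds$a_specific, file.path(outdir, "condA_specific.bed"))
write_bed(ds$b_specific, file.path(outdir, "condB_specific.bed"))
cat(sprintf("differential sites: %d condA-specific, %d condB-specific\n",
            nrow(ds$a_specific), nrow(ds$b_specific)))

rd <- ranked_density_matrix(coverage, un, "condA", "condB",
                            half_width = 1000, bin = 10)
for (s in names(rd$matrices))
  write.csv(rd$matrices[[s]],
            file.path(outdir, sprintf("density_%s.csv", s)))

prof <- normalized_average_profile(coverage, un, half_width = 1000)
cat(sprintf("profile scale factors: %s\n",
            paste(names(prof$factors), round(prof$factors, 3),
                  sep = "=", collapse = " ")))
site_sets <- list(condA_specific = ds$a_specific, union = un)
fc <- profile_fold_change(coverage, site_sets, "condA", "condB",
                          half_width = 200)
write.csv(data.frame(site_set = names(fc), log2_height_fc = fc),
          file.path(outdir, "profile_fold_change.csv"), row.names = FALSE)

bc <- binding_correlation(tm)
write.csv(bc$cor, file.path(outdir, "binding_correlation.csv"))

# motif enrichment over gained (condA-specific) vs stable union sites;
# condB-specific joins in when non-empty
stable <- un[!un$name %in% c(ds$a_specific$name, ds$b_specific$name), ]
class(stable) <- c("peak_set", "data.frame")
sets <- list(condA_specific = ds$a_specific,
             condB_specific = ds$b_specific,
             stable = stable)
sets <- Filter(function(s) nrow(s) > 0, sets)
hits <- lapply(motifs, function(mm)
  lapply(sets, function(ps) scan_pwm(genome, ps, mm)))
names(hits) <- vapply(motifs, `[[`, "", "name")
n <- count_hit_peaks(hits)
m_tot <- vapply(sets, nrow, integer(1))
es <- motif_enrichment_score(n, m_tot)
write.csv(es$S, file.path(outdir, "motif_enrichment_scores.csv"))
cat("motif enrichment scores:\n")
print(round(es$S, 3))

# spacing of the M1 motif around union summits
all_hits <- scan_pwm(genome, un, motifs[[1]], window = 400)
if (nrow(all_hits)) {
  sp <- motif_spacing_profile(un, all_hits, half_width = 200, bin = 10)
  write.csv(sp, file.path(outdir, "motif_summit_spacing.csv"),
            row.names = FALSE)
}

# gene assignment against a synthetic TSS/Hi-C annotation
set.seed(1)
tss <- data.frame(gene = sprintf("GENE%03d", 1:60), chrom = "chrS",
                  pos = sort(sample.int(glen[["chrS"]], 60)))
hic <- data.frame(chrom = "chrS",
                  start = un$summit[1:10] - 50,
                  end = un$summit[1:10] + 50,
                  gene = sprintf("HIC%02d", 1:10))
asg <- assign_peaks_to_genes(un, tss, hic)
write.table(asg, file.path(outdir, "peak_gene_assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("assignments: %s\n",
            paste(names(table(asg$source)), table(asg$source),
                  sep = "=", collapse = " ")))
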