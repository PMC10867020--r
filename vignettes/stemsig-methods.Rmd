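---
title: "Methods: signature derivation, cluster classification and chromatin scoring in stemsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature derivation, cluster classification and chromatin scoring in stemsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`stemsig` chains five analyses around one biological question: how the
quiescent leukemic stem cell (LSC) compartment of t(8;21) AML differs from
the proliferating blast compartment in gene expression, chromatin
accessibility and protein signalling state. This vignette explains each
procedure, its assumptions and tunable parameters, the numerical
conventions the implementation fixes, what the synthetic-data generators
do and do not emulate, and the design choices that were genuinely open.

## Bulk signatures

FPKM tables are **upper-quartile normalized**: sample *j* is scaled so its
75th percentile over genes with value > 0 equals the geometric mean of all
samples' upper quartiles, then log2(x + pseudocount) transformed
(`normalize_bulk()`, pseudocount default 1). The method names the
percentile but not the reference; the geometric mean was chosen because it
is symmetric in the samples and commutes with rescaling the whole panel.

`derive_lsc_blast_signature()` keeps protein-coding genes whose raw
group-mean FPKM exceeds the floor (default 1) in either sorted population
— the floor is deliberately raw-scale, mirroring a detectability filter
applied before normalization — then assigns each gene to the population
with the higher normalized mean when the **linear** ratio of
upper-quartile-normalized group means exceeds `fc_threshold`. The linear
scale matters: ratios of linear normalized means are exactly invariant to
rescaling any single sample, whereas differences of log2(x + 1) group
means are not, and the invariance is tested.

`fc_threshold` defaults to 1 — any difference separates the signatures —
because the specificity rule is stated as "fold-change above 1", which on
a linear ratio reads as any difference. A stricter 2-fold call is one
argument away; the default is not silently escalated.

`derive_subtype_specific_genes()` implements the all-versus-each rule: a
gene is subtype-specific when its target-group mean is at least `fold`
(default 2, inclusive ≥) times the mean of **every** other group
individually, not the pooled rest. Inclusive ≥ reflects the "at least
2-fold" reading; the returned list is monotone non-increasing in `fold`,
which the tests assert over {1.5, 2, 3, 4}.

## Single-cell pipeline

Order of operations: QC → log-normalize → cell-cycle score → regress/
scale/cluster → contamination filter → markers → classification. Whether
contamination filtering preceded clustering in the original workflow is
not documented; filtering after clustering was chosen because the filter
is defined on clusters.

* **QC** (`qc_filter()`): keep cells with detected genes in [200, 5000]
  — bounds inclusive, the literal complement of removing "< 200" and
  "> 5000" — and mitochondrial UMI fraction ≤ 0.15, genes flagged by the
  "MT-" name prefix.
* **Normalization** (`log_normalize()`): x → ln(1 + 10^4 · x / total).
* **Cell-cycle scores** (`score_cell_cycle()`): module score = mean
  normalized expression of the program minus the mean of control genes
  drawn per program gene from the same average-expression bin (24 bins,
  100 controls per gene, seeded draw). The bin count and control size are
  explicit parameters rather than toolkit defaults so the draw is
  reproducible. Phase: S if the S score is positive and ≥ the G2M score
  (ties go to S, an arbitrary but fixed rule), G2M if its score is
  positive and larger, else G1.
* **Regression/clustering** (`regress_scale_cluster()`): per gene, OLS
  residuals on (intercept, S score, G2M score); z-scale clipped at ±10
  (genes with residual sd below 1e-10 are set to zero rather than
  amplified); PCA (default 10 components); Jaccard-weighted shared-
  nearest-neighbour graph over 20 Euclidean neighbours, edges below 1/15
  pruned; Louvain community detection at resolution 0.8. Cells are
  processed in lexicographic barcode order internally, which makes the
  partition exactly invariant to input order; cluster ids are renumbered
  by size.
* **Markers** (`find_cluster_markers()`): Wilcoxon rank-sum of cluster vs
  rest per gene (normal approximation with tie and continuity correction,
  verified against `wilcox.test` exactly), average log2 fold-change on
  de-logged means with pseudocount 1, thresholds avg log2FC ≥ 0.25 and BH
  p < 0.1 (0.5, positive-only, for the stricter integrated list).
* **Contamination filter** (`filter_contaminant_clusters()`): clusters
  with fewer than 4 cells expressing RUNX1T1 are treated as admixed
  healthy cells and removed.
* **Z-scores** (`cluster_signature_zscore()`): per-gene Z of per-cluster
  mean expression across clusters, sample standard deviation (n − 1),
  constant rows mapped to 0; rows grouped by the cluster where they peak
  and sorted by descending Z.

Two upstream methods are out of scope and carry deliberately simple
stand-ins, both flagged in output metadata: anchor-based dataset
integration is replaced by per-batch gene-mean centering (the `batch`
argument of `regress_scale_cluster()`), and graph-learning pseudotime is
replaced by ordering clusters on their mean blast-signature module score,
most LSC-like first (`order_clusters()`) — preserving the LSC→blast axis
that downstream heatmaps need, nothing more.

### A note on cluster counts

Modularity clustering at resolution 0.8 over-partitions homogeneous
populations: on two well-separated simulated populations the partition is
a pure refinement — every cluster is 100% one population — but each
population may split in two. Seurat's FindClusters shows the same
behaviour on the same data, so this is a property of SNN/modularity
clustering at this resolution, not of this implementation. The tests
therefore assert purity and recovery of all planted populations plus a
frozen seeded cluster count, and classification operates per cluster, so
refinement does not affect downstream class calls.

## Preranked GSEA engine

`preranked_gsea()` implements the weighted Kolmogorov–Smirnov statistic
with weight exponent 1: hit increments |s|/Σ|s| over set genes, miss
decrements 1/(N − N_hit); ES is the running-sum extremum of largest
magnitude. Conventions fixed here:

* Ranking ties order lexicographically by gene id; scores must be finite
  and genes unique (`ranked_list()`).
* If all hit scores are zero the weights fall back to equal (the
  |s|⁰ limit) instead of dividing by zero.
* A ± tie of the extrema (to 1e-12) resolves positive. No deterministic
  tie rule can anti-commute with ranking reversal, so the reversal
  identity ES(−ranking) = −ES holds exactly for all non-tied cases and up
  to sign on exact ties; the tests encode precisely that.
* The null is gene-permutation: `n_perm` (default 1000) random same-size
  sets from the ranking's universe, seeded. NES divides ES by the mean
  |null ES| of matching sign; p uses the +1 correction, so p ∈
  [1/(n_perm+1), 1]. The multilevel refinement of fgsea is not
  reproduced — the classification thresholds (|NES| > 1, BH p < 0.05)
  need only permutation accuracy.
* Sign convention: the classification ranking is blast-minus-LSC, so
  positive NES means blast-like.

`classify_clusters()` runs the engine with each cluster's markers as the
set, adjusts nominal p across clusters by BH, and labels clusters
Blast / LSC / "LSC/Blast" by the NES sign and thresholds.

`de_fold_change()` covers the replicate-free count comparisons: genes
need ≥ 50 counts in at least one sample, CPM normalization, a ≥ 2-fold
(inclusive) group-mean ratio, and — when both groups have replicates — a
BH-adjusted p < 0.1 from a configurable two-sample test on log2(CPM+1).

## Chromatin

Coordinates are BED dialect throughout: 0-based half-open intervals with
single-bp summits. `merge_peak_union()` merges overlapping and bookended
intervals (distance-0 merge, the default of standard interval tooling);
the union summit comes from the highest-scoring contributing peak,
leftmost on ties. `quantify_windows()` averages per-bp coverage in
400-bp summit-centred windows; CPM divides by the sample's genome-wide
coverage total (not the in-peak total), then log2(CPM + 0.1).
`differential_sites()` applies the ≥ 2-fold rule on the log2 scale.
`ranked_density_matrix()` sorts peaks by descending fold change (offset
0.1 against empty windows; ties fall back to genomic order) and bins
coverage (±1 kb, 10-bp bins) with one shared row order across samples.
`normalized_average_profile()` defines "average peak height" as the mean
of the profile's central 10-bp bin — the operational peak when no other
definition is given — and scales every sample's height to the common
mean. `binding_correlation()` is Spearman over the union with
complete-linkage hierarchical clustering of the correlation rows for
display order; constant samples are reported as missing rather than
guessed. `assign_peaks_to_genes()` prefers a promoter-capture Hi-C
association whenever the peak overlaps a mapped fragment and otherwise
takes the nearest TSS from the summit, lexicographic gene id on exact
ties.

## Motifs

PWMs are 4×L probability matrices with per-motif log-odds thresholds in
bits; thresholds must be supplied with the motif file — there is no
silent default cutoff. Probabilities are floored at 1e-3 before the
log-odds so a legitimate base never scores −∞ (ambiguous bases do).
Scanning covers both strands of a 200-bp summit window; minus-strand hits
are reported at their plus-strand match start. The enrichment score
S_ij = (n_ij/m_j)/(Σn/Σm) counts peaks containing ≥ 1 hit — "sites that
contain the motif" reads as per-site containment — with a multiplicity
mode behind a flag for sensitivity analysis. The m-weighted mean of S
over sets is exactly 1 for any motif with hits, an identity the tests
assert to 1e-12 over random tables. Motifs with no hits anywhere are
undefined (NA) and excluded from the display clustering.

## CyTOF

Ion counts are transformed log2(x + 1); populations are compared per
marker by a two-sided two-sample t-test on transformed values (pooled
variance by default, Welch behind a flag) with significance bands
n.s. > 1e-3 ≥ * > 1e-5 ≥ ** > 1e-10 ≥ ***, cutpoints inclusive on the
small side (p = 1e-5 is **). Because the choice of transformed versus raw
means for fold displays is ambiguous in practice, both summaries are
emitted (`transform_and_summarize()`).

## The synthetic cohort

The generators (`sim_config()`, `gen_*()`) exist so every stage is
testable without downloads. Their defaults are the standard conditions
used across the tests and analysis scripts:

* **Single cell**: three populations × 500 cells over a 1,000-gene
  universe; 100 marker genes per population at log2 effect 2; the
  transition population additionally carries both pole programs at
  half effect (log2 1), making it genuinely intermediate; negative
  binomial counts (dispersion 2, log-normal depth, sd 0.3); planted S and
  G2M programs (50 genes each, log2 shift 2) with population-specific
  phase fractions (LSC mostly G1 — the quiescent compartment — blasts
  50% cycling); mitochondrial fractions uniform on [0.02, 0.08], below
  the QC cutoff; RUNX1T1 expressed in all leukemic cells.
* **Bulk**: the same marker indices planted at 4-fold in their sorted
  population over a log-normal baseline; planted genes share a fixed
  baseline of 2 so symmetric plants leave the samples' upper quartiles
  identical and noiseless recovery is exact.
* **Chromatin**: a 250-kb random genome carrying two interleaved,
  non-overlapping 100-peak sets; motif consensus insertions at per-set
  rates (default 0.3 vs 0.1 for a sharp 12-mer), positions and strands
  recorded; flat per-peak coverage from a known intensity matrix with a
  planted 3-fold gain at 20 set-A peaks, so window quantification must
  reproduce the matrix exactly.
* **CyTOF**: log-normal ion counts around 100 with planted ±1 log2
  shifts on CD38/Ki67/pJUN.

One seed determines every generator's output bit-for-bit, and ground
truth (planted genes, phases, insertion positions, intensities, shifts)
travels with the data and round-trips through serialization.

What the generators do **not** emulate — and what passing tests therefore
do not show about real data: ambient RNA and doublets, batch effects
beyond a per-patient mean shift, gene–gene correlation structure beyond
the planted programs, read-level noise (FASTQ, alignment, peak calling
are all upstream of this package), GC or accessibility bias in motif
occurrence, and CyTOF spillover or acquisition drift.

## Problem sizes

The default test and verification runs use the cohort above: 1,500 cells
× 1,000 genes per classification run (ten seeded repeats in the recovery
harness), 1,000-interval union fixtures, 200-peak scan fixtures, and
1,000-permutation GSEA nulls with 200 calibration trials. These sizes
were chosen so the planted effects dominate sampling noise while a full
verification pass stays in the minutes range on a single core.

## Known limitations

* The GSEA null is plain gene permutation; very small p-values saturate
  at 1/(n_perm + 1) rather than being refined.
* The integration and pseudotime stand-ins are intentionally minimal and
  should not be mistaken for the published methods they replace.
* Upper-quartile normalization assumes most genes are not differential
  between samples; wildly asymmetric plants would shift the reference.
* The PWM scanner is exhaustive per window and aimed at desk-scale
  genomes; it makes no attempt at genome-scale indexing.
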