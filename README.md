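# stemsig

Leukemic stem cell (LSC) and blast signature analysis for t(8;21) AML, as
a reusable, tested R workflow.

In t(8;21) (RUNX1::ETO) acute myeloid leukemia, a quiescent CD34+/CD38−
LSC population coexists with proliferating CD34+/CD38+ blasts. Comparing
the two requires a chain of bespoke computations: deriving LSC/blast gene
signatures from sorted bulk RNA-seq, classifying single-cell RNA-seq
clusters against those signatures, quantifying differential chromatin
accessibility over peak unions, scoring transcription-factor motif
enrichment across peak sets, and summarising CyTOF population statistics.
`stemsig` implements each of those steps as package functions, and ships
seeded synthetic-data generators that emulate the statistical structure of
every input, so the entire workflow runs and is verifiable at desk scale
with no external data.

## The statistics at the core

**Preranked GSEA (cluster classification).** Genes are ranked by bulk
blast-vs-LSC log2 fold-change. For a cluster's marker set, walking down
the ranking accumulates the weighted Kolmogorov–Smirnov running sum: a
set gene at rank *i* adds |s_i| / Σ|s| (sum over set genes), any other
gene subtracts 1/(N − N_hit). The enrichment score ES is the extremum of
largest magnitude; a seeded gene-permutation null of random same-size sets
yields NES = ES / mean |null ES of matching sign| and a +1-corrected
permutation p-value. A cluster is **Blast** if NES > 1 with BH-adjusted
p < 0.05, **LSC** if NES < −1 likewise, otherwise intermediate
**LSC/Blast**.

**Motif enrichment score over peak sets.** For motif *i* and peak set
*j*, with n_ij the number of peaks containing ≥ 1 hit and m_j the set
size:

    S_ij = (n_ij / m_j) / (Σ_j n_ij / Σ_j m_j)

so the m-weighted mean of S_ij over sets is exactly 1. Hits come from a
log-odds PWM scan of both strands over 200-bp summit windows.

**Differential accessibility.** Peaks called in any sample are merged
into a disjoint union (bookended intervals merge); the mean tag density in
a 400-bp window centred on each union summit is normalized as CPM and
transformed log2(CPM + 0.1); sites with ≥ 2-fold difference between
samples are condition-specific.

**Single-cell pipeline.** QC keeps cells with 200–5000 detected genes and
≤ 15% mitochondrial UMIs; log-normalization, binned-control cell-cycle
module scores, OLS regression of each gene on the S/G2M scores, per-gene
z-scaling, PCA, SNN/Louvain clustering at resolution 0.8, a RUNX1T1
contamination filter (< 4 expressing cells ⇒ cluster removed), and
rank-sum marker detection (avg log2FC ≥ 0.25, BH p < 0.1).

## Worked example

```r
library(stemsig)
run <- run_sc_classification(seed = 1)
run$summary
```

```
 cluster n_cells   true_pop        nes        padj     class
       1     276        LSC -3.3194927 0.003067485       LSC
       2     262      Blast  3.3194927 0.003067485     Blast
       3     261 Transition  0.7364192 1.000000000 LSC/Blast
       4     239 Transition  0.6330272 1.000000000 LSC/Blast
       5     238      Blast  3.2053969 0.003067485     Blast
       6     224        LSC -3.2571384 0.003067485       LSC
```

Six clusters form from the three simulated populations (Louvain at
resolution 0.8 refines each population, as the field-standard toolkits
also do); every LSC-derived cluster gets NES < −1 at adjusted p < 0.05
and is classed LSC, every blast-derived cluster the mirror image, and the
transition population — which shares half-strength expression of both
marker programs — stays intermediate.

The numbered drivers under `analysis/` run the full study workflow on the
synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1     # inputs (FPKM, MTX, BED, bedGraph, CSV)
Rscript analysis/02_bulk_signatures.R       # LSC/blast + t(8;21)-specific signatures
Rscript analysis/03_sc_classification.R 1   # single-cell pipeline + classification
Rscript analysis/04_chromatin_motifs.R 1    # peak union, differential sites, motif ES
Rscript analysis/05_cytof.R                 # CyTOF population statistics
```

Stage 5, for example, prints the blast-vs-LSC comparison with the planted
CD38/Ki67 (+1 log2) and pJUN (−1 log2) shifts recovered and banded:

```
 marker   log2_fold            p band
   CD38  1.00794551 4.237683e-93  ***
   Ki67  0.96502962 9.392228e-87  ***
   pJUN -0.93985272 1.345422e-82  ***
   CD34  0.06646300 1.255430e-01 n.s.
```

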