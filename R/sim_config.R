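# Simulation configuration.
#
# One config object drives all four generators (bulk RNA, single-cell UMI,
# chromatin/motif landscape, CyTOF).  Defaults define the standard synthetic
# cohort used throughout the tests and analysis scripts: three leukemic
# populations (quiescent LSC, a transition population, proliferating blasts)
# over a 1,000-gene universe with planted marker programs, cell-cycle
# programs, mitochondrial content, and a two-set peak landscape with known
# motif content and accessibility fold-changes.

# Gene-universe layout used by the default config (indices into n_genes):
#   1..100    LSC marker program
#   101..200  transition marker program
#   201..300  blast marker program
#   301       RUNX1T1 (fusion-partner transcript; expressed in all leukemic
#             populations, used by the contamination filter)
#   801..850  S-phase program
#   851..900  G2M program
#   981..1000 mitochondrial genes ("MT-" prefix)

#' Simulation configuration for the synthetic AML cohort
#'
#' Builds the configuration consumed by [gen_bulk_expression()],
#' [gen_sc_counts()], [gen_peak_landscape()] and [gen_cytof_table()]. All
#' randomness is governed by `seed`; identical configs produce identical
#' outputs.
#'
#' @param seed integer seed; fully determines every generator's output.
#' @param n_genes size of the shared gene universe.
#' @param n_cells_per_population single-cell population size.
#' @param populations named list of population specs; each has `markers`
#'   (gene indices), `effect` (log2 marker shift), optional `extra_markers`
#'   (list of `list(idx, effect)` secondary programs) and `cycle_fractions`
#'   (named G1/S/G2M proportions summing to 1).
#' @param s_genes,g2m_genes gene indices of the planted cell-cycle programs.
#' @param cycle_effect log2 up-shift of the phase program in cells simulated
#'   in that phase.
#' @param mito_fraction_range interval from which each cell's mitochondrial
#'   UMI fraction is drawn.
#' @param nb_dispersion negative-binomial `size` parameter (smaller = more
#'   overdispersed).
#' @param depth_sdlog log-normal spread of per-cell sequencing depth.
#' @param bulk list: `groups` (named sample counts), `planted` (list of
#'   `list(group, idx, fold)` specificity plants), `noise_sdlog`,
#'   `base_meanlog`, `base_sdlog`.
#' @param peaks list controlling [gen_peak_landscape()]: `genome_length`,
#'   `n_peaks_per_set` (named), `peak_width`, `scan_window`, `samples`,
#'   `base_intensity`, `planted` (`list(set, idx, sample, fold)`), `motifs`
#'   (list of [motif_model()]), `insertion_rates` (motifs x sets matrix).
#' @param cytof list: `markers`, `populations` (named cell counts),
#'   `base_meanlog`, `sdlog`, `shifts` (markers x populations log2 shifts).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_cells_per_population = 500L,
                       populations = NULL,
                       s_genes = 801:850,
                       g2m_genes = 851:900,
                       cycle_effect = 2,
                       mito_fraction_range = c(0.02, 0.08),
                       nb_dispersion = 2,
                       depth_sdlog = 0.3,
                       bulk = list(),
                       peaks = list(),
                       cytof = list()) {
  if (length(mito_fraction_range) != 2L ||
      any(mito_fraction_range < 0) || any(mito_fraction_range >= 1) ||
      diff(mito_fraction_range) < 0)
    abort("mito_fraction_range must be an increasing interval in [0, 1)")
  if (nb_dispersion <= 0) abort("nb_dispersion must be positive")

  if (is.null(populations)) {
    populations <- list(
      LSC = list(markers = 1:100, effect = 2,
                 cycle_fractions = c(G1 = 0.85, S = 0.08, G2M = 0.07)),
      Transition = list(markers = 101:200, effect = 2,
                        extra_markers = list(list(idx = 1:100, effect = 1),
                                             list(idx = 201:300, effect = 1)),
                        cycle_fractions = c(G1 = 0.70, S = 0.15, G2M = 0.15)),
      Blast = list(markers = 201:300, effect = 2,
                   cycle_fractions = c(G1 = 0.50, S = 0.25, G2M = 0.25)))
  }
  for (nm in names(populations)) {
    cf <- populations[[nm]]$cycle_fractions
    if (is.null(cf)) {
      populations[[nm]]$cycle_fractions <- c(G1 = 1, S = 0, G2M = 0)
    } else {
      if (abs(sum(cf) - 1) > 1e-8)
        abort("cycle_fractions for population '%s' must sum to 1", nm)
      if (any(cf < 0)) abort("cycle_fractions must be non-negative")
    }
    mk <- populations[[nm]]$markers
    if (length(mk) && (min(mk) < 1 || max(mk) > n_genes))
      abort("marker indices for '%s' outside gene universe", nm)
  }

  merge_cfg <- function(defaults, user) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  bulk <- merge_cfg(list(
    groups = c(LSC = 2L, Blast = 2L),
    planted = list(list(group = "LSC", idx = 1:100, fold = 4),
                   list(group = "Blast", idx = 201:300, fold = 4)),
    noise_sdlog = 0.25, base_meanlog = 1, base_sdlog = 1), bulk)
  planted_groups <- vapply(bulk$planted, `[[`, "", "group")
  idx_list <- lapply(bulk$planted, `[[`, "idx")
  if (length(idx_list) > 1L) {
    all_idx <- unlist(idx_list)
    if (anyDuplicated(all_idx))
      abort("planted specific gene sets must be disjoint between groups")
  }
  if (length(bulk$groups) < 2L) abort("need at least 2 bulk sample groups")
  if (!all(planted_groups %in% names(bulk$groups)))
    abort("planted group not among bulk groups")

  peaks <- merge_cfg(list(
    genome_length = 250000L,
    n_peaks_per_set = c(A = 100L, B = 100L),
    peak_width = 600L,
    scan_window = 200L,
    samples = c("condA", "condB"),
    base_intensity = 10,
    planted = list(list(set = "A", idx = 1:20, sample = "condA", fold = 3)),
    motifs = NULL,
    insertion_rates = NULL), peaks)
  if (is.null(peaks$motifs))
    peaks$motifs <- list(
      motif_model_from_consensus("M1", "TGACTCAGCATC"),
      motif_model_from_consensus("M2", "GATAAGGA"))
  if (is.null(peaks$insertion_rates)) {
    peaks$insertion_rates <- matrix(
      0, length(peaks$motifs), length(peaks$n_peaks_per_set),
      dimnames = list(vapply(peaks$motifs, `[[`, "", "name"),
                      names(peaks$n_peaks_per_set)))
    peaks$insertion_rates["M1", ] <- c(0.3, 0.1)
  }
  if (any(peaks$insertion_rates < 0) || any(peaks$insertion_rates > 1))
    abort("motif insertion rates must lie in [0, 1]")
  for (mm in peaks$motifs)
    if (ncol(mm$matrix) > peaks$scan_window)
      abort("motif '%s' longer than the peak scan window", mm$name)

  cytof <- merge_cfg(list(
    markers = c("CD34", "CD38", "CD117", "Ki67", "pJUN", "pJNK", "CD45",
                "CD11b", "CD33", "HLA-DR"),
    populations = c(LSC = 500L, Blast = 500L),
    base_meanlog = log(100), sdlog = 0.5,
    shifts = NULL), cytof)
  if (is.null(cytof$shifts)) {
    cytof$shifts <- matrix(0, length(cytof$markers),
                           length(cytof$populations),
                           dimnames = list(cytof$markers,
                                           names(cytof$populations)))
    # default plants only apply to the default marker panel
    planted_mk <- intersect(c("CD38", "Ki67", "pJUN"), cytof$markers)
    if ("Blast" %in% colnames(cytof$shifts) && length(planted_mk)) {
      up <- intersect(c("CD38", "Ki67"), planted_mk)
      cytof$shifts[up, "Blast"] <- 1
      if ("pJUN" %in% planted_mk) cytof$shifts["pJUN", "Blast"] <- -1
    }
  }

  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_cells_per_population = as.integer(n_cells_per_population),
                 populations = populations,
                 s_genes = s_genes, g2m_genes = g2m_genes,
                 cycle_effect = cycle_effect,
                 mito_fraction_range = mito_fraction_range,
                 nb_dispersion = nb_dispersion, depth_sdlog = depth_sdlog,
                 bulk = bulk, peaks = peaks, cytof = cytof),
            class = "sim_config")
}

#' Gene names of the simulated universe
#'
#' Generic genes are "G0001"-style; index 301 is RUNX1T1 and the last 20
#' indices are mitochondrial ("MT-" prefix) in the default layout.
#'
#' @param cfg a [sim_config()].
#' @return character vector of length `cfg$n_genes`.
#' @export
sim_gene_names <- function(cfg) {
  n <- cfg$n_genes
  nm <- sprintf("G%04d", seq_len(n))
  n_mt <- min(20L, n %/% 50L)
  if (n_mt > 0)
    nm[(n - n_mt + 1L):n] <- sprintf("MT-%02d", seq_len(n_mt))
  if (n >= 301L) nm[301L] <- "RUNX1T1"
  nm
}
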