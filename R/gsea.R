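# Preranked GSEA engine and cluster classification.
#
# The enrichment statistic is the weighted Kolmogorov-Smirnov running sum:
# walking down the ranking, a gene in the set increments by |score| /
# sum(|score| over set genes) and any other gene decrements by 1/(N - k).
# ES is the running-sum extremum of largest absolute value.  Significance
# comes from a seeded gene-permutation null (random same-size sets); NES
# divides ES by the mean |null ES| of matching sign, and the nominal p uses
# the +1 permutation correction so it is never exactly zero.

#' Construct a ranked gene list
#'
#' Sorts scores descending with lexicographic gene-id tie-break and checks
#' uniqueness/finiteness.
#'
#' @param scores named numeric vector (gene -> score, typically log2FC).
#' @return named numeric vector sorted descending, class `ranked_list`.
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores))) abort("ranking scores must be named by gene")
  if (anyDuplicated(names(scores))) abort("duplicate genes in ranking")
  if (any(!is.finite(scores))) abort("ranking scores must be finite")
  out <- scores[order(-scores, names(scores))]
  class(out) <- c("ranked_list", "numeric")
  out
}

#' Enrichment score at given hit positions of a sorted ranking
#'
#' Internal kernel shared by the observed statistic and the permutation
#' null: O(k) given sorted hit positions.
#' @noRd
es_at <- function(abs_scores, n, hit_pos) {
  k <- length(hit_pos)
  w <- abs_scores[hit_pos]
  sumw <- sum(w)
  if (sumw == 0) { w <- rep(1, k); sumw <- k }  # all-zero weights fallback
  miss <- 1 / (n - k)
  cum <- cumsum(w) / sumw
  # misses seen before hit i: (p_i - 1) - (i - 1) = p_i - i
  at_hit <- cum - (hit_pos - seq_len(k)) * miss
  before <- c(0, cum[-k]) - (hit_pos - seq_len(k)) * miss
  hi <- max(at_hit, 0)
  lo <- min(before, 0)
  # extremum of largest |value|; a +/- tie (to 1e-12) resolves positive
  if (abs(lo) - hi > 1e-12) lo else hi
}

#' Preranked gene set enrichment
#'
#' @param ranking a [ranked_list()] (or named numeric scores, sorted
#'   internally).
#' @param gene_set character vector of gene ids; genes absent from the
#'   ranking are ignored, but at least one must be present and the set must
#'   not cover the entire ranking.
#' @param n_perm permutations for the gene-permutation null (default 1000).
#' @param seed permutation seed.
#' @return list of class `enrichment_result`: `es`, `nes`, `p_nominal`,
#'   `n_hits`, `n_perm`, `seed`, `null_es`.
#' @export
preranked_gsea <- function(ranking, gene_set, n_perm = 1000L, seed = 0L) {
  if (!inherits(ranking, "ranked_list")) ranking <- ranked_list(ranking)
  n <- length(ranking)
  hit_pos <- sort(match(unique(gene_set), names(ranking)))
  hit_pos <- hit_pos[!is.na(hit_pos)]
  k <- length(hit_pos)
  if (k == 0L) abort("gene set shares no genes with the ranking")
  if (k == n) abort("gene set equals the entire ranking; ES undefined")
  a <- abs(as.numeric(ranking))
  es <- es_at(a, n, hit_pos)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    es_at(a, n, sort(sample.int(n, k))), numeric(1)))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  structure(list(es = es, nes = nes, p_nominal = p, n_hits = k,
                 n_perm = n_perm, seed = seed, null_es = null_es),
            class = "enrichment_result")
}

#' Combine LSC and blast signatures into a blast-high ranking
#'
#' Blast-signature genes enter with their (positive) log2fc, LSC-signature
#' genes with the negated one, so positive scores mean blast-like.
#'
#' @param lsc_sig,blast_sig [gene_signature()]s with log2fc toward their
#'   own population.
#' @return A [ranked_list()].
#' @export
signature_ranking <- function(lsc_sig, blast_sig) {
  common <- intersect(lsc_sig$genes, blast_sig$genes)
  if (length(common)) abort("signatures overlap; cannot orient ranking")
  ranked_list(c(setNames(blast_sig$log2fc, blast_sig$genes),
                setNames(-lsc_sig$log2fc, lsc_sig$genes)))
}

#' Classify single-cell clusters as LSC, Blast or intermediate
#'
#' Runs [preranked_gsea()] with each cluster's marker genes as the set
#' against a blast-minus-LSC ranking. A cluster is Blast when NES >
#' `nes_min` with BH-adjusted p (across clusters) < `padj_max`, LSC when
#' NES < `-nes_min` with adjusted p < `padj_max`, and "LSC/Blast"
#' (intermediate) otherwise.
#'
#' @param profiles list of `cluster_profile` from [find_cluster_markers()].
#' @param lsc_sig,blast_sig bulk [gene_signature()]s; used to build the
#'   ranking when `ranking` is not supplied.
#' @param nes_min absolute NES threshold (default 1).
#' @param padj_max BH-adjusted p threshold (default 0.05).
#' @param ranking optional full [ranked_list()] (e.g. [rank_genes()]
#'   output, blast-high positive); overrides the signature-built one.
#' @param n_perm,seed permutation-null parameters.
#' @return `profiles` with `class`, `nes`, `p`, `padj` filled in.
#' @export
classify_clusters <- function(profiles, lsc_sig = NULL, blast_sig = NULL,
                              nes_min = 1, padj_max = 0.05, ranking = NULL,
                              n_perm = 1000L, seed = 0L) {
  if (!length(profiles)) abort("no clusters to classify")
  if (is.null(ranking)) {
    if (is.null(lsc_sig) || is.null(blast_sig))
      abort("supply either a ranking or both signatures")
    ranking <- signature_ranking(lsc_sig, blast_sig)
  }
  if (!inherits(ranking, "ranked_list")) ranking <- ranked_list(ranking)
  res <- lapply(seq_along(profiles), function(i)
    preranked_gsea(ranking, profiles[[i]]$markers$gene, n_perm = n_perm,
                   seed = seed + i))
  p <- vapply(res, `[[`, numeric(1), "p_nominal")
  padj <- bh_adjust(p)
  for (i in seq_along(profiles)) {
    nes <- res[[i]]$nes
    cls <- "LSC/Blast"
    if (!is.na(nes) && padj[i] < padj_max) {
      if (nes > nes_min) cls <- "Blast"
      else if (nes < -nes_min) cls <- "LSC"
    }
    profiles[[i]]$class <- cls
    profiles[[i]]$nes <- nes
    profiles[[i]]$es <- res[[i]]$es
    profiles[[i]]$p <- p[i]
    profiles[[i]]$padj <- padj[i]
  }
  profiles
}

#' Propagate cluster classes to cells
#'
#' @param m a clustered [cell_matrix()].
#' @param profiles classified profiles from [classify_clusters()].
#' @return The matrix with a `class` column in `cell_meta`.
#' @export
assign_cell_classes <- function(m, profiles) {
  map <- setNames(vapply(profiles, `[[`, "", "class"),
                  vapply(profiles, `[[`, integer(1), "cluster"))
  m$cell_meta$class <- unname(map[as.character(m$cell_meta$cluster)])
  m
}
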