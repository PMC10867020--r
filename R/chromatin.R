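# Peak-union differential accessibility, density matrices, average
# profiles, binding correlation, and peak-to-gene assignment.
#
# Coverage tracks are named lists: coverage[[sample]][[chrom]] is a per-bp
# numeric vector.  CPM normalization always divides by the sample's
# genome-wide tag total (the sum of its coverage track), not the in-peak
# total.

#' Merge peak collections into a disjoint peak union
#'
#' Overlapping and bookended (distance-0) intervals merge. Each union
#' interval takes the summit of its highest-scoring contributing peak
#' (ties resolve to the leftmost summit).
#'
#' @param collections list of [peak_set()]s (a single peak_set is
#'   accepted).
#' @return A [peak_set()] of disjoint intervals named `union_<i>`.
#' @export
merge_peak_union <- function(collections) {
  if (inherits(collections, "peak_set")) collections <- list(collections)
  all_pk <- do.call(rbind, lapply(collections, as.data.frame))
  gr <- GenomicRanges::GRanges(all_pk$chrom,
                               IRanges::IRanges(all_pk$start + 1L,
                                                all_pk$end))
  red <- GenomicRanges::reduce(gr)      # merges bookended by default
  ov <- GenomicRanges::findOverlaps(red, gr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  summit <- integer(length(red))
  for (u in seq_along(red)) {
    cand <- sh[qh == u]
    best <- cand[order(-all_pk$score[cand], all_pk$summit[cand])][1]
    summit[u] <- all_pk$summit[best]
  }
  peak_set(as.character(GenomicRanges::seqnames(red)),
           GenomicRanges::start(red) - 1L, GenomicRanges::end(red),
           summit = summit,
           name = sprintf("union_%d", seq_along(red)))
}

#' Genome-wide tag total of a coverage track
#' @noRd
coverage_total <- function(cov) sum(vapply(cov, sum, numeric(1)))

#' Mean coverage in summit-centred windows
#' @noRd
window_means <- function(cov, peaks, half_width) {
  out <- numeric(nrow(peaks))
  clipped <- FALSE
  for (i in seq_len(nrow(peaks))) {
    v <- cov[[peaks$chrom[i]]]
    if (is.null(v)) abort("contig '%s' absent from coverage", peaks$chrom[i])
    w0 <- peaks$summit[i] - half_width
    w1 <- peaks$summit[i] + half_width
    if (w0 < 0L || w1 > length(v)) {
      clipped <- TRUE
      w0 <- max(w0, 0L); w1 <- min(w1, length(v))
    }
    out[i] <- mean(v[(w0 + 1L):w1])
  }
  if (clipped) warning("summit window clipped at a contig boundary")
  out
}

#' Quantify tag density over peak-union windows
#'
#' Average per-bp coverage in a `2*half_width` window centred on each union
#' summit, per sample; optionally CPM-normalized (by genome-wide tag total)
#' and log2(CPM + 0.1)-transformed.
#'
#' @param union a [peak_set()] (typically from [merge_peak_union()]).
#' @param coverages named list of coverage tracks (one per sample).
#' @param half_width window half-width in bp (default 200: a 400-bp
#'   window).
#' @param normalize `"raw"`, `"cpm"` or `"log2cpm"`.
#' @return A `tag_matrix` (peaks x samples) in the requested state.
#' @export
quantify_windows <- function(union, coverages, half_width = 200L,
                             normalize = c("raw", "cpm", "log2cpm")) {
  normalize <- match.arg(normalize)
  vals <- vapply(coverages, window_means, numeric(nrow(union)),
                 peaks = union, half_width = half_width)
  if (nrow(union) == 1L) vals <- matrix(vals, nrow = 1,
                                        dimnames = list(NULL,
                                                        names(coverages)))
  rownames(vals) <- union$name
  if (normalize != "raw") {
    totals <- vapply(coverages, coverage_total, numeric(1))
    if (any(totals == 0)) abort("sample with empty coverage track")
    vals <- sweep(vals, 2, totals, "/") * 1e6
    if (normalize == "log2cpm") vals <- log2(vals + 0.1)
  }
  tag_matrix(vals, union, normalize, half_width)
}

#' Change a tag matrix's normalization state
#'
#' @param tm a raw-state `tag_matrix`.
#' @param totals named per-sample genome-wide tag totals.
#' @param log2 also apply log2(CPM + 0.1).
#' @return The transformed `tag_matrix`.
#' @export
tag_cpm <- function(tm, totals, log2 = TRUE) {
  if (tm$state != "raw") abort("tag matrix already normalized")
  vals <- sweep(tm$values, 2, totals[colnames(tm$values)], "/") * 1e6
  if (log2) vals <- log2(vals + 0.1)
  tag_matrix(vals, tm$peaks, if (log2) "log2cpm" else "cpm", tm$half_width)
}

#' Differentially accessible/bound sites between two samples
#'
#' On log2(CPM + 0.1) values: a-specific sites satisfy
#' `log2cpm(a) - log2cpm(b) >= log2(fold)`; b-specific symmetrically.
#'
#' @param tm a `tag_matrix` in `log2cpm` state.
#' @param sample_a,sample_b column names to compare.
#' @param fold linear fold threshold (default 2).
#' @return list of two [peak_set()]s: `a_specific`, `b_specific`.
#' @export
differential_sites <- function(tm, sample_a, sample_b, fold = 2) {
  if (tm$state != "log2cpm")
    abort("differential_sites needs a log2cpm tag matrix")
  if (!all(c(sample_a, sample_b) %in% colnames(tm$values)))
    abort("unknown sample in differential comparison")
  d <- tm$values[, sample_a] - tm$values[, sample_b]
  thr <- log2(fold)
  sel_a <- d >= thr
  sel_b <- -d >= thr
  sub <- function(sel) {
    p <- tm$peaks[sel, , drop = FALSE]
    rownames(p) <- NULL
    class(p) <- c("peak_set", "data.frame")
    p
  }
  list(a_specific = sub(sel_a), b_specific = sub(sel_b))
}

#' Binned coverage matrix around summits, ranked by fold change
#'
#' Rows (peaks) are sorted by descending fold change of the average tag
#' count in `sample_a` vs `sample_b` (offset 0.1 guards empty windows; ties
#' fall back to genomic order), and every sample's matrix uses that same
#' row order, ready for side-by-side density plotting.
#'
#' @param coverages named list of coverage tracks.
#' @param peaks a [peak_set()].
#' @param sample_a,sample_b samples defining the ranking.
#' @param half_width window half-width (default 1000: +/-1 kb).
#' @param bin bin width in bp (default 10); must divide the window.
#' @return list: `order` (row permutation of `peaks`), `fold` (log2, in
#'   row order), `matrices` (per sample, peaks x bins mean coverage).
#' @export
ranked_density_matrix <- function(coverages, peaks, sample_a, sample_b,
                                  half_width = 1000L, bin = 10L) {
  if ((2L * half_width) %% bin != 0L)
    abort("bin width must divide the window")
  ma <- window_means(coverages[[sample_a]], peaks, half_width)
  mb <- window_means(coverages[[sample_b]], peaks, half_width)
  fc <- log2((ma + 0.1) / (mb + 0.1))
  ord <- order(-fc, peaks$chrom, peaks$start)
  n_bins <- (2L * half_width) %/% bin
  binned <- function(cov) {
    out <- matrix(0, nrow(peaks), n_bins)
    for (i in seq_len(nrow(peaks))) {
      v <- cov[[peaks$chrom[i]]]
      pos <- peaks$summit[i] - half_width + seq_len(2L * half_width) - 1L
      ok <- pos >= 0L & pos < length(v)
      x <- numeric(2L * half_width)
      x[ok] <- v[pos[ok] + 1L]
      out[i, ] <- colMeans(matrix(x, nrow = bin))
    }
    rownames(out) <- peaks$name
    out[ord, , drop = FALSE]
  }
  list(order = ord, fold = fc[ord],
       matrices = lapply(coverages, binned))
}

#' Per-sample average profiles with peak-height normalization
#'
#' Mean coverage per position offset over all sites, per sample. The peak
#' height is the mean of the profile's central bin (`bin` bp around the
#' summit); each sample's scale factor brings its height to the common
#' mean height of all samples.
#'
#' @param coverages named list of coverage tracks.
#' @param sites a [peak_set()] with >= 1 site.
#' @param half_width profile half-width (default 1000).
#' @param bin central-bin width for the height (default 10).
#' @return list: `profiles` (offsets x samples matrix of mean coverage),
#'   `heights`, `factors` (named per sample), `offsets`.
#' @export
normalized_average_profile <- function(coverages, sites,
                                       half_width = 1000L, bin = 10L) {
  if (nrow(sites) == 0L) abort("empty site set")
  offsets <- seq(-half_width, half_width - 1L)
  prof <- vapply(coverages, function(cov) {
    acc <- numeric(length(offsets))
    for (i in seq_len(nrow(sites))) {
      v <- cov[[sites$chrom[i]]]
      pos <- sites$summit[i] + offsets
      ok <- pos >= 0L & pos < length(v)
      x <- numeric(length(offsets))
      x[ok] <- v[pos[ok] + 1L]
      acc <- acc + x
    }
    acc / nrow(sites)
  }, numeric(length(offsets)))
  rownames(prof) <- offsets
  central <- offsets >= -(bin %/% 2L) & offsets < bin - bin %/% 2L
  heights <- colMeans(prof[central, , drop = FALSE])
  if (any(heights == 0)) abort("zero peak height; cannot normalize")
  factors <- mean(heights) / heights
  list(profiles = prof, heights = heights, factors = factors,
       offsets = offsets)
}

#' Average-peak-height fold-change heatmap over site sets
#'
#' For each site set, the log2 fold change between two samples' average
#' peak heights (central-bin means of the average profile), the statistic
#' behind condition-vs-control binding heatmaps at LSC/blast-specific
#' sites.
#'
#' @param coverages named list of coverage tracks.
#' @param site_sets named list of [peak_set()]s.
#' @param sample_a,sample_b samples to compare.
#' @param half_width,bin profile parameters.
#' @return named numeric vector: log2(height_a / height_b) per site set.
#' @export
profile_fold_change <- function(coverages, site_sets, sample_a, sample_b,
                                half_width = 1000L, bin = 10L) {
  vapply(site_sets, function(ss) {
    pr <- normalized_average_profile(coverages[c(sample_a, sample_b)],
                                     ss, half_width, bin)
    log2(pr$heights[[sample_a]] / pr$heights[[sample_b]])
  }, numeric(1))
}

#' Spearman correlation of samples over the peak union
#'
#' Pairwise Spearman rank correlation of tag counts; the display order
#' comes from complete-linkage hierarchical clustering of the Euclidean
#' distance between correlation rows. Pairs involving a constant column
#' are reported as `NA`.
#'
#' @param tm a `tag_matrix` with >= 2 samples and >= 3 peaks.
#' @return list: `cor` (samples x samples), `order` (display order).
#' @export
binding_correlation <- function(tm) {
  v <- tm$values
  if (ncol(v) < 2L || nrow(v) < 3L)
    abort("need >= 2 samples and >= 3 peaks")
  cc <- suppressWarnings(cor(v, method = "spearman"))
  const <- apply(v, 2, function(x) length(unique(x)) == 1L)
  cc[const, ] <- NA; cc[, const] <- NA
  for (j in which(!const)) cc[j, j] <- 1
  ord <- seq_len(ncol(v))
  ok <- which(!const)
  if (length(ok) > 2L) {
    hc <- hclust(dist(cc[ok, ok, drop = FALSE]), method = "complete")
    ord <- c(ok[hc$order], which(const))
  }
  list(cor = cc, order = ord)
}

#' Assign peaks to genes via Hi-C associations, else nearest TSS
#'
#' A peak overlapping a promoter-capture Hi-C fragment takes that
#' fragment's gene (even when another TSS is nearer; lexicographic winner
#' if several fragments overlap). Otherwise the gene with the TSS nearest
#' to the peak summit (absolute distance; lexicographic tie-break). Peaks
#' on chromosomes absent from the TSS table are flagged unassigned.
#'
#' @param peaks a [peak_set()].
#' @param tss data.frame with columns `gene`, `chrom`, `pos` (0-based TSS,
#'   strand-resolved by the caller).
#' @param hic_map optional data.frame `chrom`, `start`, `end`, `gene`
#'   (0-based half-open fragments).
#' @return data.frame: `peak`, `gene` (NA when unassigned), `source`
#'   (`"hic"`, `"tss"` or `"unassigned"`), `distance` (summit to TSS; NA
#'   for Hi-C assignments).
#' @export
assign_peaks_to_genes <- function(peaks, tss, hic_map = NULL) {
  out <- data.frame(peak = peaks$name, gene = NA_character_,
                    source = "unassigned", distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    if (!is.null(hic_map) && nrow(hic_map)) {
      hit <- hic_map$chrom == peaks$chrom[i] &
        hic_map$start < peaks$end[i] & hic_map$end > peaks$start[i]
      if (any(hit)) {
        out$gene[i] <- sort(hic_map$gene[hit])[1]
        out$source[i] <- "hic"
        next
      }
    }
    cand <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    d <- abs(cand$pos - peaks$summit[i])
    best <- which(d == min(d))
    pick <- best[order(cand$gene[best])][1]
    out$gene[i] <- cand$gene[pick]
    out$source[i] <- "tss"
    out$distance[i] <- d[pick]
  }
  out
}
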