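# PWM models, motif scanning, and the peak-set motif enrichment score.
#
# The enrichment score for motif i over peak sets j is
#   S_ij = (n_ij / m_j) / (sum_j n_ij / sum_j m_j)
# where n_ij is the number of peaks in set j containing >= 1 motif hit and
# m_j the number of peaks in set j.  By construction the m-weighted mean of
# S_ij over sets is exactly 1 for any motif with at least one hit.

BASES <- c("A", "C", "G", "T")

#' Construct a position-weight-matrix motif model
#'
#' @param name motif label.
#' @param matrix 4 x L base-probability matrix (rows A, C, G, T); columns
#'   must sum to 1 (tolerance 1e-6), L >= 4.
#' @param threshold log-odds hit threshold in bits; a scan position is a hit
#'   when its score reaches the threshold. Must be supplied with the motif
#'   (no silent default cutoff).
#' @param background base frequencies used for the log-odds (default
#'   uniform 0.25).
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(name, matrix, threshold, background = rep(0.25, 4)) {
  if (nrow(matrix) != 4L) abort("motif matrix must have 4 rows (A,C,G,T)")
  if (ncol(matrix) < 4L) abort("motif '%s' shorter than 4 bp", name)
  if (any(abs(colSums(matrix) - 1) > 1e-6))
    abort("motif '%s': columns must sum to 1", name)
  if (!is.finite(threshold)) abort("motif '%s': threshold must be finite", name)
  rownames(matrix) <- BASES
  structure(list(name = name, matrix = matrix,
                 threshold = as.numeric(threshold),
                 background = as.numeric(background)),
            class = "motif_model")
}

#' Build a sharp motif model from a consensus string
#'
#' Consensus bases get probability `p_match`, the rest share the remainder.
#' The default threshold (80% of the maximal attainable log-odds score)
#' admits only exact consensus matches for the default `p_match`.
#'
#' @param name motif label.
#' @param consensus string over A/C/G/T.
#' @param p_match probability mass on the consensus base per position.
#' @param threshold hit threshold in bits; default `0.8 * max score`.
#' @return A [motif_model()].
#' @export
motif_model_from_consensus <- function(name, consensus, p_match = 0.97,
                                       threshold = NULL) {
  b <- strsplit(toupper(consensus), "")[[1]]
  if (!all(b %in% BASES)) abort("consensus must be over A/C/G/T")
  L <- length(b)
  mat <- matrix((1 - p_match) / 3, 4, L, dimnames = list(BASES, NULL))
  mat[cbind(match(b, BASES), seq_len(L))] <- p_match
  lo <- log2(pmax(mat, 1e-3) / 0.25)
  max_score <- sum(apply(lo, 2, max))
  if (is.null(threshold)) threshold <- 0.8 * max_score
  motif_model(name, mat, threshold)
}

#' Log-odds matrix of a motif (probabilities floored at 1e-3)
#' @noRd
motif_logodds <- function(mm) {
  log2(pmax(mm$matrix, 1e-3) / mm$background)
}

#' Reverse complement of a log-odds matrix
#' @noRd
logodds_revcomp <- function(lo) {
  lo[4:1, ncol(lo):1, drop = FALSE]
}

#' Write motif models in the package text format
#'
#' One record per motif: a header line `>name consensus threshold` followed
#' by L rows of four base probabilities (A C G T).
#'
#' @param motifs list of [motif_model()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mm in motifs) {
    cons <- paste(BASES[apply(mm$matrix, 2, which.max)], collapse = "")
    writeLines(sprintf(">%s %s %.6g", mm$name, cons, mm$threshold), con)
    write.table(format(t(mm$matrix), digits = 6), con, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read motif models written by [write_motifs()]
#'
#' @param path motif text file.
#' @return list of [motif_model()].
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) abort("no motif headers ('>name ...') in %s", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  lapply(seq_along(hdr), function(i) {
    fields <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]]
    rows <- lines[(hdr[i] + 1L):ends[i]]
    rows <- rows[nzchar(trimws(rows))]
    mat <- t(vapply(unname(rows),
                    function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4)))
    motif_model(fields[1], unname(t(mat)), as.numeric(fields[3]))
  })
}

#' Scan peak windows for motif hits on both strands
#'
#' Scores every position of a window centred on each peak summit against the
#' motif's log-odds matrix (background default uniform), on both strands,
#' and reports positions scoring at or above the motif threshold. Ambiguous
#' bases (N) give -Inf. Windows extending past a contig end are clipped
#' with a warning.
#'
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param peaks a [peak_set()].
#' @param motif a [motif_model()].
#' @param window scan-window width in bp centred on the summit (default
#'   200); `Inf` scans the whole peak.
#' @return data.frame with columns `peak`, `pos` (0-based genome position
#'   of the match start), `offset` (pos - summit), `strand`, `score`.
#' @export
scan_pwm <- function(genome, peaks, motif, window = 200L) {
  seqs <- if (is.character(genome)) genome else
    setNames(as.character(genome), names(genome))
  if (is.null(names(seqs))) abort("genome sequences must be named")
  lo <- motif_logodds(motif)
  lorc <- logodds_revcomp(lo)
  L <- ncol(lo)
  out <- vector("list", nrow(peaks))
  clipped <- FALSE
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(seqs)) abort("contig '%s' absent from genome", chrom)
    clen <- nchar(seqs[[chrom]])
    if (is.finite(window)) {
      w0 <- peaks$summit[i] - window %/% 2L
      w1 <- w0 + window
    } else {
      w0 <- peaks$start[i]; w1 <- peaks$end[i]
    }
    if (w0 < 0L || w1 > clen) {
      clipped <- TRUE
      w0 <- max(w0, 0L); w1 <- min(w1, clen)
    }
    if (w1 - w0 < L) next
    sub <- substr(seqs[[chrom]], w0 + 1L, w1)
    code <- match(strsplit(sub, "")[[1]], BASES)  # NA for N etc.
    np <- length(code) - L + 1L
    sc_f <- sc_r <- numeric(np)
    for (l in seq_len(L)) {
      b <- code[l:(l + np - 1L)]
      add_f <- ifelse(is.na(b), -Inf, lo[cbind(b, l)])
      add_r <- ifelse(is.na(b), -Inf, lorc[cbind(b, l)])
      sc_f <- sc_f + add_f
      sc_r <- sc_r + add_r
    }
    hf <- which(sc_f >= motif$threshold)
    hr <- which(sc_r >= motif$threshold)
    if (length(hf) + length(hr)) {
      pos <- c(w0 + hf - 1L, w0 + hr - 1L)
      out[[i]] <- data.frame(
        peak = peaks$name[i], pos = pos,
        offset = pos - peaks$summit[i],
        strand = rep(c("+", "-"), c(length(hf), length(hr))),
        score = c(sc_f[hf], sc_r[hr]), stringsAsFactors = FALSE)
    }
  }
  if (clipped) warning("scan window clipped at a contig boundary")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(peak = character(), pos = integer(),
                      offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Motif enrichment scores over peak sets
#'
#' Computes `S_ij = (n_ij/m_j) / (sum_j n_ij / sum_j m_j)` from per-set
#' hit-bearing peak counts, with complete-linkage hierarchical clustering
#' (Euclidean distance) of the score rows for display order. Motifs with no
#' hits in any set have undefined scores (`NA`) and are excluded from
#' clustering.
#'
#' @param n motifs x sets matrix of hit-bearing peak counts, or a list of
#'   scan results (see [count_hit_peaks()]).
#' @param m named per-set peak totals.
#' @return list of class `motif_enrichment` with elements `S`, `n`, `m`,
#'   `order` (motif display order).
#' @export
motif_enrichment_score <- function(n, m) {
  n <- as.matrix(n)
  if (!is.null(names(m)) && !is.null(colnames(n))) m <- m[colnames(n)]
  m <- as.numeric(m)
  if (any(m == 0)) abort("every peak set must be non-empty (m_j > 0)")
  if (any(n < 0) || any(n > rep(m, each = nrow(n))))
    abort("need 0 <= n_ij <= m_j")
  tot <- rowSums(n) / sum(m)
  S <- sweep(n, 2, m, "/") / tot          # rows with tot == 0 become NaN
  S[rowSums(n) == 0, ] <- NA_real_
  ord <- seq_len(nrow(S))
  defined <- which(rowSums(n) > 0)
  if (length(defined) > 2L) {
    hc <- hclust(dist(S[defined, , drop = FALSE]), method = "complete")
    ord <- c(defined[hc$order], setdiff(ord, defined))
  }
  structure(list(S = S, n = n, m = setNames(m, colnames(n)), order = ord),
            class = "motif_enrichment")
}

#' Count hit-bearing peaks per motif and per peak set
#'
#' @param hits nested list: `hits[[motif]][[set]]` scan result data.frames
#'   from [scan_pwm()].
#' @param multiplicity if `TRUE` count total hits instead of hit-bearing
#'   peaks (sensitivity mode; the default counts each peak at most once).
#' @return motifs x sets integer matrix `n`.
#' @export
count_hit_peaks <- function(hits, multiplicity = FALSE) {
  motifs <- names(hits)
  sets <- names(hits[[1]])
  n <- matrix(0L, length(motifs), length(sets),
              dimnames = list(motifs, sets))
  for (i in motifs) for (j in sets) {
    h <- hits[[i]][[j]]
    n[i, j] <- if (multiplicity) nrow(h) else length(unique(h$peak))
  }
  n
}

#' Binned spacing profile of partner-motif hits around anchor hits
#'
#' For every peak carrying an anchor hit, tabulates partner positions
#' relative to the anchor into fixed-width bins over `[-half_width,
#' half_width)`. A loess smooth of the binned frequencies is attached for
#' display; raw bin counts are always returned.
#'
#' @param anchor_hits scan result ([scan_pwm()]) providing anchor positions;
#'   alternatively a [peak_set()] whose summits serve as anchors.
#' @param partner_hits scan result providing partner positions.
#' @param half_width profile half-width in bp (default 1000).
#' @param bin bin width in bp (default 10); must divide `2*half_width`.
#' @return data.frame with `mid` (bin midpoint), `count`, `freq`, `smooth`.
#' @export
motif_spacing_profile <- function(anchor_hits, partner_hits,
                                  half_width = 1000L, bin = 10L) {
  if ((2L * half_width) %% bin != 0L)
    abort("bin width must divide the profile window")
  if (inherits(anchor_hits, "peak_set"))
    anchor_hits <- data.frame(peak = anchor_hits$name,
                              pos = anchor_hits$summit)
  if (nrow(anchor_hits) == 0L) abort("no anchor hits")
  rel <- numeric(0)
  common <- intersect(unique(anchor_hits$peak), unique(partner_hits$peak))
  for (pk in common) {
    a <- anchor_hits$pos[anchor_hits$peak == pk]
    p <- partner_hits$pos[partner_hits$peak == pk]
    rel <- c(rel, as.vector(outer(p, a, "-")))
  }
  rel <- rel[rel >= -half_width & rel < half_width]
  breaks <- seq(-half_width, half_width, by = bin)
  cnt <- as.vector(table(cut(rel, breaks, right = FALSE)))
  out <- data.frame(mid = breaks[-length(breaks)] + bin / 2, count = cnt,
                    freq = if (length(rel)) cnt / length(rel) else 0)
  out$smooth <- tryCatch(
    predict(loess(freq ~ mid, data = out, span = 0.3)),
    error = function(e) out$freq)
  out
}
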