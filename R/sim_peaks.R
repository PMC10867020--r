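# Synthetic chromatin landscape: genome, peak sets with planted motifs,
# and per-sample fragment coverage with known per-peak intensities.

#' Generate a synthetic genome, peak sets and coverage tracks
#'
#' Builds a random single-contig genome ("chrS"), lays down the configured
#' non-overlapping peak sets on a regular grid, inserts each motif's
#' consensus into a seeded random subset of peaks (per-set insertion rate,
#' uniform offset within the summit scan window, uniform strand), and
#' constructs flat per-peak coverage for each sample from a known intensity
#' matrix, so that accessibility fold-changes between samples are known
#' exactly.
#'
#' @param cfg a [sim_config()]; see the `peaks` sub-config.
#' @return list of class `peak_landscape`: `genome` (named character),
#'   `peaks` (named list of [peak_set()]), `coverage` (per-sample list of
#'   per-contig numeric vectors), `intensity` (peaks x samples matrix, rows
#'   named `set:peak`), `insertions` (data.frame of planted motif
#'   instances), `config` echo.
#' @export
gen_peak_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pc <- cfg$peaks
  glen <- pc$genome_length
  width <- pc$peak_width
  sets <- names(pc$n_peaks_per_set)
  n_total <- sum(pc$n_peaks_per_set)
  gap <- glen %/% (n_total + 1L) - width
  if (gap < 10L) abort("genome too short for the requested peaks")

  with_seed(cfg$seed + 303L, {
    genome_chars <- sample(BASES, glen, replace = TRUE)

    # peaks on a grid, alternating nothing between sets (sets interleave
    # along the contig but never overlap)
    starts <- (seq_len(n_total) - 1L) * (width + gap) + gap %/% 2L
    set_of <- rep(sets, times = pc$n_peaks_per_set)
    peaks <- list()
    for (s in sets) {
      idx <- which(set_of == s)
      peaks[[s]] <- peak_set(chrom = "chrS", start = starts[idx],
                             end = starts[idx] + width,
                             name = sprintf("%s_%03d", s, seq_along(idx)))
    }

    # plant motif consensus sequences
    ins <- list()
    for (mi in seq_along(pc$motifs)) {
      mm <- pc$motifs[[mi]]
      cons <- BASES[apply(mm$matrix, 2, which.max)]
      L <- length(cons)
      for (s in sets) {
        rate <- pc$insertion_rates[mm$name, s]
        if (rate == 0) next
        ps <- peaks[[s]]
        chosen <- which(runif(nrow(ps)) < rate)
        for (k in chosen) {
          half <- pc$scan_window %/% 2L
          off <- sample.int(pc$scan_window - L + 1L, 1L) - 1L - half
          pos <- ps$summit[k] + off     # 0-based match start
          strand <- sample(c("+", "-"), 1L)
          piece <- if (strand == "+") cons else rev(BASES[5L - match(cons, BASES)])
          genome_chars[(pos + 1L):(pos + L)] <- piece
          ins[[length(ins) + 1L]] <- data.frame(
            motif = mm$name, set = s, peak = ps$name[k], pos = pos,
            offset = off, strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
    insertions <- if (length(ins)) do.call(rbind, ins) else
      data.frame(motif = character(), set = character(), peak = character(),
                 pos = integer(), offset = integer(), strand = character())

    # per-peak, per-sample intensity: flat coverage over the whole peak
    all_peaks <- do.call(rbind, lapply(sets, function(s)
      cbind(set = s, as.data.frame(peaks[[s]]))))
    intensity <- matrix(pc$base_intensity, nrow(all_peaks),
                        length(pc$samples),
                        dimnames = list(paste0(all_peaks$set, ":",
                                               all_peaks$name),
                                        pc$samples))
    for (pl in pc$planted) {
      rows <- which(all_peaks$set == pl$set)[pl$idx]
      intensity[rows, pl$sample] <- intensity[rows, pl$sample] * pl$fold
    }
    coverage <- lapply(pc$samples, function(sm) {
      v <- numeric(glen)
      for (r in seq_len(nrow(all_peaks)))
        v[(all_peaks$start[r] + 1L):all_peaks$end[r]] <- intensity[r, sm]
      list(chrS = v)
    })
    names(coverage) <- pc$samples
  })

  structure(list(genome = c(chrS = paste(genome_chars, collapse = "")),
                 peaks = peaks, coverage = coverage, intensity = intensity,
                 insertions = insertions,
                 config = list(seed = cfg$seed, peaks = pc[setdiff(names(pc),
                                                                   "motifs")])),
            class = "peak_landscape")
}

#' Write a peak landscape to disk (FASTA, BED, bedGraph, truth JSON)
#'
#' @param land output of [gen_peak_landscape()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_sim_peaks <- function(land, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- Biostrings::DNAStringSet(land$genome)
  Biostrings::writeXStringSet(gen, file.path(dir, "genome.fa"))
  for (s in names(land$peaks))
    write_bed(land$peaks[[s]], file.path(dir, sprintf("peaks_%s.bed", s)))
  for (sm in names(land$coverage))
    write_bedgraph(land$coverage[[sm]],
                   file.path(dir, sprintf("coverage_%s.bedGraph", sm)))
  jsonlite::write_json(
    list(insertions = land$insertions,
         intensity = as.data.frame(land$intensity),
         intensity_rows = rownames(land$intensity),
         seed = land$config$seed),
    file.path(dir, "peaks_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
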