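# Plain-text genomics I/O: BED6+summit, narrowPeak, bedGraph, FASTA.
# Coordinates are BED dialect throughout: 0-based half-open [start, end);
# summits are absolute 0-based positions.

#' Write a peak_set as BED6 + absolute-summit column
#'
#' Columns: chrom, start, end, name, score, strand (`.`), summit.
#'
#' @param peaks a [peak_set()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   peaks$score, rep(".", nrow(peaks)), peaks$summit)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from BED or narrowPeak
#'
#' Accepts BED3+ (summit defaults to the interval midpoint), the package's
#' BED6+summit layout (7th column = absolute summit), or narrowPeak (10
#' columns; summit = start + column-10 offset). Malformed intervals raise a
#' parse error naming the offending line.
#'
#' @param path BED-like file.
#' @param format `"auto"` (by column count), `"bed"`, or `"narrowPeak"`.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  nc <- ncol(df)
  if (format == "auto")
    format <- if (nc == 10L) "narrowPeak" else "bed"
  bad <- which(df[[2]] >= df[[3]])
  if (length(bad))
    abort("malformed interval (start >= end) at line %d of %s", bad[1], path)
  name <- if (nc >= 4L) as.character(df[[4]]) else NULL
  score <- if (nc >= 5L) as.numeric(df[[5]]) else NULL
  summit <- NULL
  if (format == "narrowPeak") {
    off <- df[[10]]
    summit <- ifelse(off >= 0, df[[2]] + off, df[[2]] + (df[[3]] - df[[2]]) %/% 2L)
  } else if (nc >= 7L) {
    summit <- df[[7]]
  }
  peak_set(df[[1]], df[[2]], df[[3]], summit = summit, score = score,
           name = name)
}

#' Write per-contig coverage vectors as bedGraph
#'
#' Consecutive equal values are collapsed into runs; zero runs are omitted.
#'
#' @param cov named list of per-contig numeric vectors (per-bp coverage).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(cov, path) {
  rows <- list()
  for (chrom in names(cov)) {
    v <- cov[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      rows[[chrom]] <- data.frame(chrom, starts[keep], ends[keep],
                                  r$values[keep])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character(), integer(), integer(), numeric())
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into per-contig coverage vectors
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param contig_lengths named integer vector giving each contig's length;
#'   inferred from the maximum end coordinate if omitted.
#' @return named list of per-contig numeric vectors.
#' @export
read_bedgraph <- function(path, contig_lengths = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  chroms <- unique(df$chrom)
  if (is.null(contig_lengths))
    contig_lengths <- vapply(chroms, function(ch)
      max(df$end[df$chrom == ch]), numeric(1))
  cov <- lapply(chroms, function(ch) {
    v <- numeric(contig_lengths[[ch]])
    sub <- df[df$chrom == ch, ]
    for (i in seq_len(nrow(sub)))
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    v
  })
  names(cov) <- chroms
  cov
}

#' Read a genome FASTA as a named character vector
#'
#' @param path FASTA file (one or more files may be concatenated by the
#'   caller; contigs keep their header names).
#' @return named character vector of contig sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}
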