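# Mass-cytometry population statistics.
#
# Ion counts are log2(x + 1)-transformed; population comparisons use
# two-sided two-sample t-tests on the transformed values with significance
# bands at p <= 1e-3 (*), <= 1e-5 (**), <= 1e-10 (***); larger p is n.s.
# Band cutpoints are inclusive on the small side (p = 1e-5 is **).

#' Transform ion counts and summarise per-population marker means
#'
#' @param t an `ion_table` (see [gen_cytof_table()]).
#' @return list: `log2_means` (populations x markers, mean of log2(x+1)),
#'   `raw_means` (populations x markers, arithmetic mean of raw counts,
#'   kept for log2-mean-ion-count displays).
#' @export
transform_and_summarize <- function(t) {
  pops <- unique(t$population)
  for (p in pops)
    if (!sum(t$population == p)) abort("empty population '%s'", p)
  lg <- log2(t$counts + 1)
  log2_means <- t(vapply(pops, function(p)
    colMeans(lg[t$population == p, , drop = FALSE]),
    numeric(ncol(t$counts))))
  raw_means <- t(vapply(pops, function(p)
    colMeans(t$counts[t$population == p, , drop = FALSE]),
    numeric(ncol(t$counts))))
  rownames(log2_means) <- rownames(raw_means) <- pops
  list(log2_means = log2_means, raw_means = raw_means)
}

#' Map p-values to significance bands
#'
#' @param p numeric p-values.
#' @return character bands: `"n.s."` (p > 1e-3), `"*"` (<= 1e-3),
#'   `"**"` (<= 1e-5), `"***"` (<= 1e-10).
#' @export
significance_band <- function(p) {
  ifelse(p <= 1e-10, "***",
         ifelse(p <= 1e-5, "**",
                ifelse(p <= 1e-3, "*", "n.s.")))
}

#' Compare two populations per marker
#'
#' Reports, per marker, the difference of mean log2(x+1) ion counts
#' (`pop_a` minus `pop_b`) and a two-sided two-sample t-test p-value on the
#' transformed values, banded by [significance_band()].
#'
#' @param t an `ion_table`.
#' @param pop_a,pop_b population labels; both need >= 2 cells.
#' @param var_equal pooled-variance Student's t (default `TRUE`); `FALSE`
#'   gives Welch's t.
#' @return data.frame: `marker`, `log2_fold` (a - b), `p`, `band`.
#' @export
compare_populations <- function(t, pop_a, pop_b, var_equal = TRUE) {
  ia <- which(t$population == pop_a)
  ib <- which(t$population == pop_b)
  if (length(ia) < 2L || length(ib) < 2L)
    abort("both populations need at least 2 cells")
  lg <- log2(t$counts + 1)
  res <- lapply(colnames(t$counts), function(mk) {
    xa <- lg[ia, mk]; xb <- lg[ib, mk]
    fold <- mean(xa) - mean(xb)
    if (var(xa) == 0 && var(xb) == 0) {
      p <- if (mean(xa) == mean(xb)) 1 else 0
    } else {
      p <- t.test(xa, xb, var.equal = var_equal)$p.value
    }
    data.frame(marker = mk, log2_fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$band <- significance_band(out$p)
  out
}

#' Population-pair fold heatmap matrix
#'
#' Log2 fold differences of mean transformed ion counts for every ordered
#' population pair, heatmap-ready (pairs x markers).
#'
#' @param t an `ion_table`.
#' @return matrix with one row per ordered population pair ("A_vs_B").
#' @export
population_fold_heatmap <- function(t) {
  pops <- unique(t$population)
  if (length(pops) < 2L)
    abort("fold heatmap undefined for a single population")
  sm <- transform_and_summarize(t)$log2_means
  pairs <- t(combn(pops, 2))
  out <- matrix(0, nrow(pairs), ncol(sm),
                dimnames = list(paste0(pairs[, 1], "_vs_", pairs[, 2]),
                                colnames(sm)))
  for (i in seq_len(nrow(pairs)))
    out[i, ] <- sm[pairs[i, 1], ] - sm[pairs[i, 2], ]
  out
}
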