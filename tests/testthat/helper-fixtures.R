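# Shared fixtures: small configurations and independent oracles used across
# test files.  Oracles are deliberately naive (per-bp masks, step-by-step
# running sums, per-cell recounts) and independent of the package internals.

# Small two-population single-cell config (fast pipeline runs)
small_sc_config <- function(seed = 1, n_cells = 150, ...) {
  sim_config(seed = seed, n_cells_per_population = n_cells,
             populations = list(
               LSC = list(markers = 1:100, effect = 2,
                          cycle_fractions = c(G1 = 0.85, S = 0.08,
                                              G2M = 0.07)),
               Blast = list(markers = 201:300, effect = 2,
                            cycle_fractions = c(G1 = 0.5, S = 0.25,
                                                G2M = 0.25))),
             ...)
}

# Run QC -> normalize -> score on a generated matrix
prep_sc <- function(m, seed = 7) {
  gt <- attr(m, "ground_truth")
  m <- suppressMessages(qc_filter(m))
  m <- log_normalize(m)
  score_cell_cycle(m, gt$s_genes, gt$g2m_genes, seed = seed)
}

# Step-by-step weighted KS running-sum oracle for the GSEA statistic.
# Walks every ranking position; returns the extremum of largest |value|
# (+/- ties resolve positive, matching the engine's documented rule).
es_oracle <- function(scores, set_genes) {
  genes <- names(scores)
  hit <- genes %in% set_genes
  k <- sum(hit)
  n <- length(scores)
  w <- abs(scores[hit])
  if (sum(w) == 0) w <- rep(1, k)
  w <- w / sum(w)
  running <- 0
  hi <- 0
  lo <- 0
  wi <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      wi <- wi + 1
      running <- running + w[wi]
    } else {
      running <- running - 1 / (n - k)
    }
    hi <- max(hi, running)
    lo <- min(lo, running)
  }
  # same tie rule as the engine: +/- ties (1e-12) resolve positive
  unname(if (abs(lo) - hi > 1e-12) lo else hi)
}

# Per-bp boolean-mask oracle for interval unions (single chromosome)
mask_oracle <- function(start, end, len) {
  mask <- logical(len)
  for (i in seq_along(start)) mask[(start[i] + 1):end[i]] <- TRUE
  mask
}

# Brute-force naive PWM scanner: scores every window position on both
# strands by explicit per-base lookup
naive_scan <- function(seq_str, motif, from0, to0) {
  lo <- log2(pmax(motif$matrix, 1e-3) / motif$background)
  L <- ncol(lo)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  for (p0 in from0:(to0 - L)) {
    sub <- strsplit(substr(seq_str, p0 + 1, p0 + L), "")[[1]]
    sc_f <- 0; sc_r <- 0
    for (l in seq_len(L)) {
      b <- sub[l]
      sc_f <- sc_f + (if (b %in% rownames(lo)) lo[b, l] else -Inf)
      rb <- comp[[sub[L + 1 - l]]]
      sc_r <- sc_r + (if (rb %in% rownames(lo)) lo[rb, l] else -Inf)
    }
    if (sc_f >= motif$threshold)
      hits[[length(hits) + 1]] <- data.frame(pos = p0, strand = "+",
                                             score = sc_f)
    if (sc_r >= motif$threshold)
      hits[[length(hits) + 1]] <- data.frame(pos = p0, strand = "-",
                                             score = sc_r)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(pos = integer(), strand = character(), score = numeric())
}

# Wrap a bare peaks x samples matrix as a tag_matrix (internal container)
tag_matrix_for_test <- function(vals, state = "raw") {
  ps <- peak_set("chrS", seq(0, by = 1000, length.out = nrow(vals)),
                 seq(600, by = 1000, length.out = nrow(vals)))
  stemsig:::tag_matrix(vals, ps, state, 200)
}

# Tiny deterministic coverage track builder
flat_cov <- function(len, intervals, values) {
  v <- numeric(len)
  for (i in seq_along(values))
    v[(intervals[[i]][1] + 1):intervals[[i]][2]] <- values[i]
  list(chrS = v)
}
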