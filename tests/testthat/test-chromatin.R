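# Peak unions, window quantification, differential sites, density
# matrices, profiles, correlation, gene assignment.

test_that("peak union merges overlapping and bookended intervals", {
  a <- peak_set("chrS", c(10, 40), c(20, 60), score = c(5, 1))
  b <- peak_set("chrS", 20, 30, score = 9)
  un <- merge_peak_union(list(a, b))
  # [10,20) and [20,30) are bookended -> one interval [10,30)
  expect_identical(un$start, c(10L, 40L))
  expect_identical(un$end, c(30L, 60L))
  # summit comes from the highest-scoring contributor (score 9)
  expect_identical(un$summit[1], b$summit[1])
  # disjoint input passes through sorted
  d <- merge_peak_union(peak_set("chrS", c(100, 5), c(150, 8)))
  expect_identical(d$start, c(5L, 100L))
  # idempotence
  expect_identical(merge_peak_union(un)[, c("chrom", "start", "end")],
                   un[, c("chrom", "start", "end")])
})

test_that("union length and membership match a per-bp mask oracle", {
  set.seed(91)
  for (trial in 1:4) {
    n <- 250
    start <- sample(0:4000, n, replace = TRUE)
    end <- start + sample(1:120, n, replace = TRUE)
    ps <- peak_set("chrS", start, end)
    un <- merge_peak_union(ps)
    mask <- mask_oracle(start, end, 5000)
    expect_identical(sum(un$end - un$start), sum(mask))
    mask2 <- mask_oracle(un$start, un$end, 5000)
    expect_identical(mask2, mask)
    # disjointness (no bookended pairs survive)
    expect_true(all(un$start[-1] > un$end[-nrow(un)]))
  }
})

test_that("window quantification: constants, additivity, CPM invariance", {
  ps <- peak_set("chrS", c(100, 500), c(300, 700))
  cov1 <- list(s1 = flat_cov(1000, list(c(100, 300), c(500, 700)), c(4, 8)))
  tm <- quantify_windows(ps, cov1, half_width = 50)
  expect_equal(unname(tm$values[, 1]), c(4, 8))
  # additivity of raw quantification
  cov2 <- list(s1 = flat_cov(1000, list(c(100, 300), c(500, 700)), c(1, 2)))
  tm2 <- quantify_windows(ps, cov2, half_width = 50)
  covsum <- list(s1 = list(chrS = cov1$s1$chrS + cov2$s1$chrS))
  tmsum <- quantify_windows(ps, covsum, half_width = 50)
  expect_equal(tmsum$values, tm$values + tm2$values)
  # doubling a sample's coverage leaves CPM unchanged
  both <- list(a = cov1$s1, b = list(chrS = 2 * cov1$s1$chrS))
  cpm <- quantify_windows(ps, both, half_width = 50, normalize = "cpm")
  expect_equal(cpm$values[, "a"], cpm$values[, "b"], tolerance = 1e-12)
  # off-contig windows clip with a warning
  edge <- peak_set("chrS", 0, 40, summit = 5)
  expect_warning(quantify_windows(edge, cov1, half_width = 50), "clipped")
})

test_that("differential sites: identity, antisymmetry, planted recovery", {
  cfg <- sim_config(seed = 95)
  land <- gen_peak_landscape(cfg)
  un <- merge_peak_union(land$peaks)
  tm <- quantify_windows(un, land$coverage, 200, normalize = "log2cpm")
  # identical samples -> both lists empty
  same <- quantify_windows(un, list(x = land$coverage[[1]],
                                    y = land$coverage[[1]]),
                           200, normalize = "log2cpm")
  ds0 <- differential_sites(same, "x", "y")
  expect_identical(nrow(ds0$a_specific), 0L)
  expect_identical(nrow(ds0$b_specific), 0L)
  # swap antisymmetry
  d1 <- differential_sites(tm, "condA", "condB")
  d2 <- differential_sites(tm, "condB", "condA")
  expect_identical(d1$a_specific$name, d2$b_specific$name)
  expect_identical(d1$b_specific$name, d2$a_specific$name)
  # planted 3-fold peaks (set A, first 20) are exactly the a-specific set
  planted <- sprintf("A_%03d", 1:20)
  got <- un$name[un$summit %in%
                   land$peaks$A$summit[land$peaks$A$name %in% planted]]
  expect_setequal(d1$a_specific$name, got)
  expect_error(differential_sites(tm, "condA", "nope"), "unknown")
  # brute-force re-check of the rule on the matrix itself
  thr <- log2(2)
  expect_setequal(d1$a_specific$name,
                  rownames(tm$values)[tm$values[, "condA"] -
                                        tm$values[, "condB"] >= thr])
})

test_that("ranked density matrix sorts rows by an independent fold ranking", {
  cfg <- sim_config(seed = 97)
  land <- gen_peak_landscape(cfg)
  un <- merge_peak_union(land$peaks)
  rd <- ranked_density_matrix(land$coverage, un, "condA", "condB",
                              half_width = 200, bin = 10)
  # oracle: sort the window-mean fold vector independently
  wm <- function(cov) vapply(seq_len(nrow(un)), function(i) {
    v <- cov$chrS[(un$summit[i] - 200 + 1):(un$summit[i] + 200)]
    mean(v)
  }, numeric(1))
  fc <- log2((wm(land$coverage$condA) + 0.1) /
               (wm(land$coverage$condB) + 0.1))
  expect_equal(rd$fold, sort(fc, decreasing = TRUE), tolerance = 1e-12)
  # all-equal folds fall back to genomic order
  same <- list(a = land$coverage$condA, b = land$coverage$condA)
  rd0 <- ranked_density_matrix(same, un, "a", "b", half_width = 200,
                               bin = 10)
  expect_identical(rd0$order, seq_len(nrow(un)))
  # single peak, uniform coverage: all bins equal
  ps1 <- peak_set("chrS", 1000, 1600)
  cov1 <- list(s = flat_cov(5000, list(c(0, 5000)), 3))
  rd1 <- ranked_density_matrix(cov1, ps1, "s", "s", half_width = 100,
                               bin = 10)
  expect_equal(unname(rd1$matrices$s[1, ]), rep(3, 20))
  expect_error(ranked_density_matrix(cov1, ps1, "s", "s",
                                     half_width = 100, bin = 7), "divide")
})

test_that("average profiles recover scale factors and intensity ratios", {
  ps <- peak_set("chrS", c(200, 700), c(400, 900))
  base <- flat_cov(2000, list(c(200, 400), c(700, 900)), c(6, 6))
  covs <- list(a = base, b = list(chrS = 2 * base$chrS))
  pr <- normalized_average_profile(covs, ps, half_width = 100)
  # identical samples scale to 1; a 2x sample gets half the factor
  expect_equal(unname(pr$factors["a"] / pr$factors["b"]), 2,
               tolerance = 1e-12)
  scaled <- sweep(pr$profiles, 2, pr$factors, "*")
  expect_equal(scaled[, "a"], scaled[, "b"], tolerance = 1e-12)
  same <- normalized_average_profile(list(x = base, y = base), ps, 100)
  expect_equal(unname(same$factors), c(1, 1))
  # fold-change heatmap equals the configured intensity ratio
  cfg <- sim_config(seed = 99)
  land <- gen_peak_landscape(cfg)
  sets <- list(planted = land$peaks$A[1:20, ],
               flat = land$peaks$B[1:20, ])
  class(sets$planted) <- class(sets$flat) <- c("peak_set", "data.frame")
  fc <- profile_fold_change(land$coverage, sets, "condA", "condB",
                            half_width = 100)
  expect_equal(unname(fc["planted"]), log2(3), tolerance = 1e-12)
  expect_equal(unname(fc["flat"]), 0, tolerance = 1e-12)
  expect_error(normalized_average_profile(covs, ps[0, ], 100), "empty")
})

test_that("binding correlation equals rank-then-Pearson and orders samples", {
  set.seed(101)
  vals <- matrix(rlnorm(100 * 5), 100, 5,
                 dimnames = list(NULL, paste0("s", 1:5)))
  vals[, 2] <- vals[, 1] * 3          # monotone transform of s1
  tm <- tag_matrix_for_test(vals)
  bc <- binding_correlation(tm)
  # oracle: rank each column, then Pearson
  oracle <- cor(apply(vals, 2, rank))
  expect_equal(bc$cor, oracle, tolerance = 1e-12)
  expect_equal(bc$cor["s1", "s2"], 1)
  # constant column reported missing
  vals2 <- vals; vals2[, 3] <- 7
  bc2 <- binding_correlation(tag_matrix_for_test(vals2))
  expect_true(all(is.na(bc2$cor[3, ])))
  expect_true(all(is.na(bc2$cor[, 3])))
  expect_error(binding_correlation(tag_matrix_for_test(vals[1:2, 1,
                                                            drop = FALSE])),
               "samples")
})

test_that("peak-to-gene assignment prefers Hi-C and ties lexicographically", {
  peaks <- peak_set("chr1", c(100, 1000, 5000), c(200, 1100, 5100),
                    summit = c(150, 1050, 5050))
  tss <- data.frame(gene = c("B", "A", "C"), chrom = "chr1",
                    pos = c(160, 2000, 4000))
  # peak 1: nearest TSS is B (10 bp); Hi-C maps it to A -> A wins
  hic <- data.frame(chrom = "chr1", start = 140, end = 180, gene = "A")
  out <- assign_peaks_to_genes(peaks, tss, hic)
  expect_identical(out$gene[1], "A")
  expect_identical(out$source[1], "hic")
  # no Hi-C: brute-force nearest-TSS scan agrees
  out2 <- assign_peaks_to_genes(peaks, tss)
  brute <- vapply(seq_len(nrow(peaks)), function(i) {
    d <- abs(tss$pos - peaks$summit[i])
    tss$gene[order(d, tss$gene)][1]
  }, "")
  expect_identical(out2$gene, brute)
  # equidistant summit: lexicographically smaller gene wins
  tss_tie <- data.frame(gene = c("Z", "Y"), chrom = "chr1",
                        pos = c(1000, 1100))
  tie <- assign_peaks_to_genes(peak_set("chr1", 1000, 1100, summit = 1050),
                               tss_tie)
  expect_identical(tie$gene, "Y")
  # unknown chromosome flagged unassigned
  off <- assign_peaks_to_genes(peak_set("chrX", 10, 20), tss)
  expect_identical(off$source, "unassigned")
  expect_true(is.na(off$gene))
})

test_that("peaks round-trip through BED and narrowPeak, bedGraph through
          coverage", {
  dir <- withr::local_tempdir()
  ps <- peak_set("chrS", c(10, 100), c(60, 180), summit = c(30, 140),
                 score = c(2, 5))
  p <- file.path(dir, "x.bed")
  write_bed(ps, p)
  back <- read_peaks(p)
  expect_equal(as.data.frame(back), as.data.frame(ps))
  # narrowPeak: summit = start + column-10 offset
  np <- file.path(dir, "x.narrowPeak")
  writeLines(c("chrS\t10\t60\tp1\t0\t.\t1\t2\t3\t15",
               "chrS\t100\t180\tp2\t0\t.\t1\t2\t3\t-1"), np)
  pk <- read_peaks(np)
  expect_identical(pk$summit, c(25L, 140L))  # offset 15; -1 -> midpoint
  expect_error(read_peaks({
    bad <- file.path(dir, "bad.bed")
    writeLines("chrS\t50\t40\tp\t0\t.\t45", bad)
    bad
  }), "line 1")
  # bedGraph round trip
  cov <- flat_cov(500, list(c(10, 60), c(100, 180)), c(2.5, 4))
  bg <- file.path(dir, "x.bedGraph")
  write_bedgraph(cov, bg)
  cov2 <- read_bedgraph(bg, contig_lengths = c(chrS = 500))
  expect_equal(cov2$chrS, cov$chrS)
})
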