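# PWM scanning and the peak-set motif enrichment score.

test_that("planted motif instances are found at their offsets and strands", {
  cfg <- sim_config(seed = 111)
  land <- gen_peak_landscape(cfg)
  mot <- cfg$peaks$motifs[[1]]
  for (s in c("A", "B")) {
    hits <- scan_pwm(land$genome, land$peaks[[s]], mot)
    ins <- land$insertions[land$insertions$set == s &
                             land$insertions$motif == "M1", ]
    merged <- merge(ins, hits, by = "peak")
    expect_identical(nrow(merged), nrow(ins))
    expect_true(all(merged$offset.x == merged$offset.y))
    expect_true(all(merged$strand.x == merged$strand.y))
  }
})

test_that("scan equals a naive full-enumeration scanner including chance hits", {
  cfg <- sim_config(seed = 113)
  land <- gen_peak_landscape(cfg)
  # the shorter M2 motif is never planted by default: only chance hits
  mot <- cfg$peaks$motifs[[2]]
  hits <- scan_pwm(land$genome, land$peaks$A, mot)
  naive <- list()
  for (i in seq_len(nrow(land$peaks$A))) {
    p <- land$peaks$A[i, ]
    nv <- naive_scan(land$genome[["chrS"]], mot,
                     p$summit - 100, p$summit + 100)
    if (nrow(nv)) naive[[i]] <- cbind(peak = p$name, nv)
  }
  naive <- if (length(naive)) do.call(rbind, naive) else
    data.frame(peak = character(), pos = integer(), strand = character())
  expect_identical(nrow(hits), nrow(naive))
  if (nrow(hits)) {
    o1 <- hits[order(hits$pos, hits$strand), ]
    o2 <- naive[order(naive$pos, naive$strand), ]
    expect_identical(o1$pos, as.integer(o2$pos))
    expect_identical(o1$strand, o2$strand)
    expect_equal(o1$score, o2$score, tolerance = 1e-10)
  }
})

test_that("strand symmetry: reverse-complemented genome flips strands", {
  cfg <- sim_config(seed = 115)
  land <- gen_peak_landscape(cfg)
  mot <- cfg$peaks$motifs[[1]]
  hits <- scan_pwm(land$genome, land$peaks$A, mot)
  # reverse complement the genome and mirror the peaks
  glen <- nchar(land$genome[["chrS"]])
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(land$genome[["chrS"]],
                                                  "")[[1]]), collapse = ""))
  pk <- land$peaks$A
  mirror <- peak_set("chrS", glen - pk$end, glen - pk$start,
                     summit = glen - 1L - pk$summit, name = pk$name)
  hits_rc <- scan_pwm(c(chrS = rc), mirror, mot)
  expect_identical(nrow(hits_rc), nrow(hits))
  expect_identical(sum(hits_rc$strand == "+"), sum(hits$strand == "-"))
})

test_that("unsatisfiable thresholds and long motifs are handled", {
  cfg <- sim_config(seed = 117)
  land <- gen_peak_landscape(cfg)
  mot <- cfg$peaks$motifs[[1]]
  hi <- motif_model(mot$name, mot$matrix, threshold = 1e6)
  expect_identical(nrow(scan_pwm(land$genome, land$peaks$A, hi)), 0L)
  expect_error(sim_config(peaks = list(scan_window = 8L)), "longer")
})

test_that("the enrichment score matches the two-set hand fixture", {
  n <- matrix(c(30, 10), 1, 2, dimnames = list("M", c("A", "B")))
  es <- motif_enrichment_score(n, c(A = 100, B = 100))
  expect_equal(unname(es$S["M", ]), c(1.5, 0.5))
  # m-weighted mean is exactly 1
  expect_equal(sum(c(100, 100) / 200 * es$S["M", ]), 1)
  # single peak set collapses to S = 1
  one <- motif_enrichment_score(matrix(5, 1, 1,
                                       dimnames = list("M", "A")),
                                c(A = 10))
  expect_equal(unname(one$S[1, 1]), 1)
  expect_error(motif_enrichment_score(n, c(A = 0, B = 100)), "non-empty")
  expect_error(motif_enrichment_score(matrix(c(11, 0), 1, 2), c(10, 10)),
               "n_ij")
})

test_that("the weighted-mean identity holds on random tables and scaling
          leaves S unchanged", {
  set.seed(119)
  for (trial in 1:20) {
    m <- sample(50:400, 4)
    n <- matrix(0L, 6, 4, dimnames = list(paste0("M", 1:6), LETTERS[1:4]))
    for (i in 1:6) n[i, ] <- vapply(m, function(mm)
      sample.int(mm + 1, 1) - 1L, integer(1))
    es <- motif_enrichment_score(n, m)
    w <- m / sum(m)
    defined <- rowSums(n) > 0
    expect_true(all(abs(es$S[defined, , drop = FALSE] %*% w - 1) < 1e-12))
    expect_true(all(is.na(es$S[!defined, ])))
    # common scaling of n and m leaves S invariant
    es3 <- motif_enrichment_score(n * 3, m * 3)
    expect_equal(es3$S, es$S, tolerance = 1e-12)
  }
})

test_that("hit-multiplicity mode counts hits, default counts peaks", {
  h <- data.frame(peak = c("p1", "p1", "p2"), pos = 1:3,
                  offset = 0, strand = "+", score = 1)
  hits <- list(M = list(A = h))
  expect_identical(count_hit_peaks(hits)["M", "A"], 2L)
  expect_identical(count_hit_peaks(hits, multiplicity = TRUE)["M", "A"], 3L)
})

test_that("spacing profiles recover planted spacings and mirror correctly", {
  anchors <- data.frame(peak = sprintf("p%02d", 1:40),
                        pos = seq(1000, by = 3000, length.out = 40))
  partners <- data.frame(peak = anchors$peak, pos = anchors$pos + 55)
  pr <- motif_spacing_profile(anchors, partners, half_width = 200, bin = 10)
  expect_identical(sum(pr$count), 40L)
  expect_identical(pr$mid[which.max(pr$count)], 55)
  # mirrored positions reverse the profile exactly (offsets +/-55 fall in
  # mirror-image half-open bins)
  partners_m <- data.frame(peak = anchors$peak, pos = anchors$pos - 55)
  pr_m <- motif_spacing_profile(anchors, partners_m, half_width = 200,
                                bin = 10)
  expect_identical(rev(pr_m$count), pr$count)
  expect_identical(pr_m$mid[which.max(pr_m$count)], -55)
  # flat null: uniform random partners give no dominant bin
  set.seed(121)
  partners_u <- data.frame(
    peak = rep(anchors$peak, each = 20),
    pos = rep(anchors$pos, each = 20) +
      sample(-200:199, 40 * 20, replace = TRUE))
  pr_u <- motif_spacing_profile(anchors, partners_u, half_width = 200,
                                bin = 10)
  expect_lt(max(pr_u$freq), 5 / length(pr_u$freq))
  expect_error(motif_spacing_profile(anchors[0, ], partners, 200, 10),
               "anchor")
})

test_that("motif models round-trip through the text format", {
  dir <- withr::local_tempdir()
  mots <- list(motif_model_from_consensus("AP1", "TGACTCA"),
               motif_model_from_consensus("GATA", "AGATAAGG",
                                          threshold = 9.5))
  p <- file.path(dir, "motifs.txt")
  write_motifs(mots, p)
  back <- read_motifs(p)
  expect_identical(length(back), 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$name, mots[[i]]$name)
    expect_equal(back[[i]]$matrix, mots[[i]]$matrix, tolerance = 1e-5)
    expect_equal(back[[i]]$threshold, mots[[i]]$threshold,
                 tolerance = 1e-5)
  }
  expect_error(motif_model("bad", matrix(0.5, 4, 3), 1), "shorter")
  expect_error(motif_model("bad", matrix(0.3, 4, 6), 1), "sum to 1")
})
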