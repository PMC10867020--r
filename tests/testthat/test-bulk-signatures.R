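# Upper-quartile normalization and signature derivation.

test_that("upper-quartile normalization equalizes nonzero 75th percentiles", {
  set.seed(21)
  vals <- matrix(rlnorm(200 * 4, 1, 1), 200, 4,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  vals[sample(length(vals), 60)] <- 0
  tab <- expr_table(vals, rep(c("A", "B"), each = 2))
  norm <- normalize_bulk(tab, pseudocount = 1)
  # undo the log and recompute the percentile with an independent
  # type-7 quantile on the nonzero entries of each sample
  lin <- 2^norm$values - 1
  q <- apply(lin, 2, function(x) {
    nz <- sort(x[x > 1e-9])
    h <- (length(nz) - 1) * 0.75
    nz[floor(h) + 1] + (h - floor(h)) * (nz[floor(h) + 2] - nz[floor(h) + 1])
  })
  expect_equal(unname(q), rep(unname(q[1]), 4), tolerance = 1e-8)
})

test_that("normalization identities: identical and scaled samples", {
  vals <- matrix(rlnorm(100 * 2, 1, 1), 100, 2,
                 dimnames = list(sprintf("g%03d", 1:100), c("a", "b")))
  vals[, 2] <- vals[, 1]
  tab <- expr_table(vals, c("A", "B"))
  norm <- normalize_bulk(tab)
  expect_equal(attr(norm, "uq_factors"), rep(1, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(norm$values[, 1], norm$values[, 2])
  # one sample at 2x the other normalizes to equality
  vals2 <- vals; vals2[, 2] <- 2 * vals2[, 1]
  norm2 <- normalize_bulk(expr_table(vals2, c("A", "B")))
  expect_equal(norm2$values[, 1], norm2$values[, 2], tolerance = 1e-12)
  # all-zero sample is a named error
  vals3 <- vals; vals3[, 2] <- 0
  expect_error(normalize_bulk(expr_table(vals3, c("A", "B"))), "b")
})

test_that("LSC/blast derivation applies the floor and fold rules", {
  # hand-built 4-gene table: low/low, equal, LSC-up, Blast-up
  vals <- matrix(c(0.5, 0.5, 0.5, 0.5,    # below floor in both
                   5, 5, 5, 5,            # equal
                   8, 8, 2, 2,            # LSC-specific
                   2, 2, 8, 8),           # Blast-specific
                 nrow = 4, byrow = TRUE,
                 dimnames = list(c("low", "flat", "lsc_up", "blast_up"),
                                 c("L1", "L2", "B1", "B2")))
  tab <- expr_table(vals, c("LSC", "LSC", "Blast", "Blast"))
  sig <- derive_lsc_blast_signature(tab)
  expect_identical(sig$lsc$genes, "lsc_up")
  expect_identical(sig$blast$genes, "blast_up")
  # signatures are disjoint by construction
  expect_length(intersect(sig$lsc$genes, sig$blast$genes), 0)
  expect_error(derive_lsc_blast_signature(
    expr_table(vals, c("X", "X", "Y", "Y"))), "LSC")
})

test_that("planted signatures are recovered exactly on noiseless tables", {
  cfg <- sim_config(seed = 31, bulk = list(noise_sdlog = 0))
  tab <- gen_bulk_expression(cfg)
  gt <- attr(tab, "ground_truth")
  sig <- derive_lsc_blast_signature(tab)
  expect_setequal(sig$lsc$genes, gt$planted$LSC)
  expect_setequal(sig$blast$genes, gt$planted$Blast)
})

test_that("subtype rule is all-versus-each with inclusive >=", {
  # g1: 2-fold above everything; g2: 2-fold above one group, 1.5 above the
  # other -> excluded; g3: exactly at fold -> included
  vals <- matrix(c(8, 4, 4,      # 2-fold vs both others
                   6, 3, 4,      # 2-fold vs s2, 1.5-fold vs s3
                   8, 4, 2),     # exactly 2-fold vs s2 (max other)
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("t821", "inv16", "NPM1")))
  tab <- expr_table(vals, c("t821", "inv16", "NPM1"))
  # neutralize upper-quartile scaling so the hand arithmetic holds
  sig <- derive_subtype_specific_genes(tab, "t821", fold = 2)
  f <- attr(normalize_bulk(tab), "uq_factors")
  lin <- sweep(vals, 2, f, "*")
  expected <- rownames(vals)[
    lin[, 1] >= 2 * pmax(lin[, 2], lin[, 3])]
  expect_setequal(sig$genes, expected)
  expect_error(derive_subtype_specific_genes(tab, "absent"), "absent")
})

test_that("subtype derivation matches a brute-force all-pairs oracle and is
          monotone in fold", {
  cfg <- sim_config(seed = 33, bulk = list(
    groups = c(t821 = 2L, inv16 = 2L, NPM1 = 2L, PBSC = 2L),
    planted = list(list(group = "t821", idx = 1:50, fold = 4)),
    noise_sdlog = 0.15))
  tab <- gen_bulk_expression(cfg)
  sig <- derive_subtype_specific_genes(tab, "t821", fold = 2)
  # brute force: per gene, compare target mean against each group mean
  f <- attr(normalize_bulk(tab), "uq_factors")
  lin <- sweep(tab$values, 2, f, "*")
  expected <- character(0)
  for (g in rownames(lin)) {
    tm <- mean(lin[g, tab$groups == "t821"])
    ok <- TRUE
    for (other in c("inv16", "NPM1", "PBSC"))
      if (tm < 2 * mean(lin[g, tab$groups == other])) ok <- FALSE
    if (ok) expected <- c(expected, g)
  }
  expect_setequal(sig$genes, expected)
  # noiseless recovery is exact
  cfg0 <- sim_config(seed = 34, bulk = list(
    groups = c(t821 = 2L, inv16 = 2L, NPM1 = 2L, PBSC = 2L),
    planted = list(list(group = "t821", idx = 1:50, fold = 4)),
    noise_sdlog = 0))
  tab0 <- gen_bulk_expression(cfg0)
  sig0 <- derive_subtype_specific_genes(tab0, "t821", fold = 2)
  expect_setequal(sig0$genes, attr(tab0, "ground_truth")$planted$t821)
  # monotone non-increasing in the fold parameter
  sizes <- vapply(c(1.5, 2, 3, 4), function(f)
    length(derive_subtype_specific_genes(tab, "t821", fold = f)$genes),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("scaling a single sample leaves both derivations unchanged", {
  cfg <- sim_config(seed = 35, bulk = list(noise_sdlog = 0.1))
  tab <- gen_bulk_expression(cfg)
  scaled <- tab$values; scaled[, 1] <- scaled[, 1] * 7
  tab2 <- expr_table(scaled, tab$groups)
  # ratio decisions are exactly invariant; the raw-FPKM expression floor is
  # deliberately raw-scale, so disable it to isolate the normalization
  sig <- derive_lsc_blast_signature(tab, fpkm_floor = 0)
  sig2 <- derive_lsc_blast_signature(tab2, fpkm_floor = 0)
  expect_setequal(sig2$lsc$genes, sig$lsc$genes)
  expect_setequal(sig2$blast$genes, sig$blast$genes)
  sub <- derive_subtype_specific_genes(tab, "LSC", fold = 2)
  sub2 <- derive_subtype_specific_genes(tab2, "LSC", fold = 2)
  expect_setequal(sub2$genes, sub$genes)
  # planted calls survive the floor in both runs
  sigf <- derive_lsc_blast_signature(tab)
  sigf2 <- derive_lsc_blast_signature(tab2)
  gt <- attr(tab, "ground_truth")
  expect_true(all(gt$planted$LSC %in% sigf$lsc$genes))
  expect_true(all(gt$planted$LSC %in% sigf2$lsc$genes))
})

test_that("signatures round-trip through TSV", {
  dir <- withr::local_tempdir()
  sig <- gene_signature("LSC", c("g1", "g2"), c(1.5, -0.3))
  p <- file.path(dir, "lsc.tsv")
  write_signature(sig, p)
  back <- read_signature(p)
  expect_identical(back$genes, sig$genes)
  expect_equal(back$log2fc, sig$log2fc)
  expect_identical(back$name, "LSC")
})
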