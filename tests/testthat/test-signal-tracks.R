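test_that("pileup applies shift/extension semantics per strand", {
  cs <- chrom_sizes(c(chr1 = 2000))
  # one + tag cut at 1000, shift -75, extsize 150 -> unit coverage on [925, 1075)
  tag <- tag_table("chr1", 1000, 1050, "+", 60)
  tr <- pileup(tag, cs, pileup_config(spmr = FALSE))
  v <- tr$chr1
  expect_equal(which(v > 0), 926:1075)    # 1-based view of [925, 1075)
  expect_true(all(v[926:1075] == 1))
  # SPMR with a single-tag library scales the window to 1e6
  trs <- pileup(tag, cs, pileup_config(spmr = TRUE))
  expect_equal(unique(trs$chr1[926:1075]), 1e6)
  # additivity without SPMR
  tr2 <- pileup(rbind(tag, tag), cs, pileup_config(spmr = FALSE))
  expect_equal(tr2$chr1[1000], 2)
  # minus strand mirrored: cut at end-1 = 999, window centred there
  tagm <- tag_table("chr1", 950, 1000, "-", 60)
  trm <- pileup(tagm, cs, pileup_config(spmr = FALSE))
  expect_equal(sum(trm$chr1), 150)
  expect_equal(which(trm$chr1 > 0), 926:1075)
})

test_that("pileup conserves mass and clips at chromosome ends", {
  cs <- chrom_sizes(c(chr1 = 10000))
  set.seed(3)
  n <- 200
  pos <- sample(500:9500, n, replace = TRUE)
  tags <- tag_table("chr1", pos, pos + 50,
                    sample(c("+", "-"), n, replace = TRUE), 60)
  tr <- pileup(tags, cs, pileup_config(spmr = FALSE))
  expect_equal(sum(tr$chr1), n * 150)          # no clipping: n * extsize
  # SPMR total mass = extsize * 1e6
  trs <- pileup(tags, cs, pileup_config(spmr = TRUE))
  expect_equal(sum(trs$chr1), 150 * 1e6)
  # clipping: a tag cut at position 0 loses the upstream half
  edge <- tag_table("chr1", 0, 50, "+", 60)
  tre <- pileup(edge, cs, pileup_config(spmr = FALSE))
  expect_equal(sum(tre$chr1), 75)
  expect_true(all(tre$chr1 >= 0))
})

test_that("binned correlation is exact for identity and scale", {
  cs_len <- c(chr1 = 50000)
  set.seed(8)
  v <- rpois(50000, 2)
  t1 <- uniform_track(0, cs_len); t1$chr1 <- as.numeric(v)
  t2 <- t1; t2$chr1 <- 2 * t1$chr1
  r <- binned_correlation(list(a = t1, b = t1, c = t2), bin_bp = 1000)
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), 1)        # scale invariance
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))
  # independent tracks decorrelate
  t3 <- t1; t3$chr1 <- as.numeric(rpois(50000, 2))
  r2 <- binned_correlation(list(a = t1, b = t3), bin_bp = 10)
  expect_lt(abs(r2["a", "b"]), 0.05)
  # zero-variance track -> NA off-diagonal
  t0 <- uniform_track(1, cs_len)
  r3 <- suppressWarnings(binned_correlation(list(a = t1, b = t0)))
  expect_true(is.na(r3["a", "b"]))
})

test_that("metagene matrix handles uniform signal, TSS spikes and strand", {
  genes <- make_test_genes()
  cfg <- metagene_config(upstream = 1000, downstream = 1000,
                         body_bp = 2000, bin_bp = 10, skip_zeros = FALSE)
  # uniform coverage -> every cell equal
  tru <- uniform_track(3, c(chr1 = 1e5))
  mg <- metagene_matrix(tru, genes, cfg)
  expect_true(all(mg$matrix == 3))
  expect_equal(dim(mg$matrix), c(2, 400))
  # signal only at the TSS of the + gene appears at the first body column
  tr <- uniform_track(0, c(chr1 = 1e5))
  tr$chr1[20001:20010] <- 5                  # [20000,20010) = gA TSS bin
  mg2 <- metagene_matrix(tr, genes, cfg)
  expect_equal(which(mg2$matrix["gA", ] > 0), unname(mg2$bin_labels["tss"]))
  # same construction for the - strand gene lands on the same column
  tr3 <- uniform_track(0, c(chr1 = 1e5))
  tr3$chr1[67991:68000] <- 5                 # [67990,68000) = gB TSS bin
  mg3 <- metagene_matrix(tr3, genes, cfg)
  expect_equal(which(mg3$matrix["gB", ] > 0), unname(mg3$bin_labels["tss"]))
  # skip_zeros drops silent genes
  cfg2 <- metagene_config(upstream = 1000, downstream = 1000,
                          body_bp = 2000, bin_bp = 10, skip_zeros = TRUE)
  expect_equal(rownames(metagene_matrix(tr, genes, cfg2)$matrix), "gA")
})

test_that("TSS enrichment is 1 for uniform tracks and ~2 for doubled cores", {
  genes <- make_test_genes()
  tru <- uniform_track(4, c(chr1 = 1e5))
  expect_equal(tss_enrichment(tru, genes), 1, tolerance = 1e-9)
  # coverage doubled within +/-50 bp of each TSS
  tr <- uniform_track(2, c(chr1 = 1e5))
  for (i in seq_len(nrow(genes))) {
    w <- (genes$tss[i] - 50):(genes$tss[i] + 50)
    tr[[genes$chrom[i]]][w + 1] <- 4
  }
  expect_equal(tss_enrichment(tr, genes), 2, tolerance = 0.05)
  expect_error(tss_enrichment(tru, genes[0, ]), "1")
  # zero track -> NA with warning
  tr0 <- uniform_track(0, c(chr1 = 1e5))
  expect_warning(s <- tss_enrichment(tr0, genes), "zero signal")
  expect_true(is.na(s))
})
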