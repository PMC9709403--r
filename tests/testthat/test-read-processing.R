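test_that("MAPQ filtering is strict at the threshold", {
  tags <- tag_table("chr1", c(0, 10, 20), c(50, 60, 70),
                    c("+", "+", "-"), mapq = c(4, 5, 60))
  res <- filter_tags(tags, filter_config(mapq_min = 5))
  expect_equal(nrow(res$tags), 2)          # mapq 4 dropped, mapq 5 kept
  expect_equal(res$tags$mapq, c(5, 60))
  expect_equal(unname(res$stats["dropped_mapq"]), 1)
  # empty input
  empty <- filter_tags(tags[0, ], filter_config())
  expect_equal(nrow(empty$tags), 0)
  expect_equal(unname(empty$stats["input"]), 0)
})

test_that("filtering drops unknown and (optionally) organelle chromosomes", {
  cs <- chrom_sizes(c(chr1 = 1000, chrMt = 100))
  tags <- tag_table(c("chr1", "chrMt", "scaffold9"), c(0, 0, 0),
                    c(50, 50, 50), "+", 60)
  res <- filter_tags(tags, filter_config(), cs)
  expect_equal(nrow(res$tags), 2)
  expect_equal(unname(res$stats["dropped_unknown_chrom"]), 1)
  res2 <- filter_tags(tags, filter_config(drop_organelle = TRUE), cs)
  expect_equal(res2$tags$chrom, "chr1")
})

test_that("deduplication keys on strand-specific cut site", {
  # 4 copies of one cut-site key + 6 distinct
  dup <- tag_table("chr1", rep(100, 4), rep(150, 4), "+", 60)
  distinct <- tag_table("chr1", seq(200, 700, by = 100),
                        seq(250, 750, by = 100), "+", 60)
  res <- deduplicate(rbind(dup, distinct))
  expect_equal(nrow(res$tags), 7)
  cm <- res$complexity
  expect_equal(unname(cm["NRF"]), 0.7)
  expect_equal(unname(cm["distinct_positions"]), 7)
  expect_equal(unname(cm["one_read_positions"]), 6)
  expect_equal(unname(cm["PBC1"]), 6 / 7)
  # PBC2 infinite when nothing occurs exactly twice
  expect_equal(unname(cm["PBC2"]), Inf)
  # same 5' cut but different end is still a duplicate on "cut" keying...
  v <- rbind(tag_table("chr1", 100, 150, "+", 60),
             tag_table("chr1", 100, 175, "+", 60))
  expect_equal(nrow(deduplicate(v)$tags), 1)
  # ...but not on interval keying
  expect_equal(nrow(deduplicate(v, key = "interval")$tags), 2)
  # opposite strands never collide: cut sites differ in meaning
  w <- rbind(tag_table("chr1", 100, 150, "+", 60),
             tag_table("chr1", 100, 150, "-", 60))
  expect_equal(nrow(deduplicate(w)$tags), 2)
})

test_that("deduplication is idempotent and all-distinct input passes through", {
  tags <- tag_table("chr1", seq(0, 900, 100), seq(50, 950, 100),
                    rep(c("+", "-"), 5), 60)
  r1 <- deduplicate(tags)
  expect_equal(unname(r1$complexity["NRF"]), 1)
  expect_equal(unname(r1$complexity["PBC1"]), 1)
  r2 <- deduplicate(r1$tags)
  expect_equal(r2$tags, r1$tags)
})

test_that("complexity counts conserve the tag multiset", {
  set.seed(7)
  for (d in c(0, 0.2, 0.5)) {
    n <- 2000
    n_orig <- round(n * (1 - d))
    pos <- sample.int(5e4, n_orig, replace = TRUE)
    pos <- c(pos, sample(pos, n - n_orig, replace = TRUE))
    tags <- tag_table("chr1", pos, pos + 50, "+", 60)
    cm <- deduplicate(tags)$complexity
    # one + 2*two + higher multiplicities account for every tag
    higher <- cm["total_tags"] - cm["one_read_positions"] -
      2 * cm["two_read_positions"]
    expect_gte(unname(higher), 0)
    expect_equal(unname(cm["total_tags"]), n)
  }
  # NRF decreases monotonically with duplicate rate
  nrf <- vapply(c(0, 0.2, 0.5), function(d) {
    set.seed(11)
    n_orig <- round(2000 * (1 - d))
    pos <- seq_len(n_orig) * 20
    pos <- c(pos, sample(pos, 2000 - n_orig, replace = TRUE))
    unname(deduplicate(tag_table("chr1", pos, pos + 50, "+", 60))$complexity["NRF"])
  }, numeric(1))
  expect_true(all(diff(nrf) < 0))
})

test_that("organelle fraction is the organelle tag share", {
  cs <- chrom_sizes(c(chr1 = 1e4, chrMt = 1e3))
  tags <- tag_table(c(rep("chr1", 95), rep("chrMt", 5)),
                    0:99 * 10, 0:99 * 10 + 50, "+", 60)
  expect_equal(organelle_fraction(tags, cs), 0.05)
  expect_equal(organelle_fraction(tags, chrom_sizes(c(chr1 = 1e4,
                                                      other = 1e3))), 0)
  expect_warning(z <- organelle_fraction(tags[0, ], cs), "no tags")
  expect_equal(z, 0)
})

test_that("simulated contamination rate is recovered", {
  sim <- simulate_library(sim_config(seed = 5, n_fragments = 25000,
                                     contamination = 0.3, n_genes = 40,
                                     chrom_lengths = c(chr1 = 4e5,
                                                       chr2 = 4e5,
                                                       chrMt = 5e4)))
  est <- organelle_fraction(sim$tags, sim$chrom_sizes)
  expect_lt(abs(est - 0.3), 0.01)
})
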