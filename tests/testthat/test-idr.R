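test_that("pseudo-replicate splits conserve the multiset and the seed", {
  sim <- simulate_library(sim_config(seed = 3, n_fragments = 5000,
                                     n_genes = 10,
                                     chrom_lengths = c(chr1 = 2e5)))
  tags <- sim$tags
  sp <- split_pseudoreplicates(tags, seed = 11)
  expect_lte(abs(nrow(sp$a) - nrow(sp$b)), 1)
  expect_equal(nrow(sp$a) + nrow(sp$b), nrow(tags))
  # multiset conservation: sorted concatenation equals sorted input
  key <- function(df) sort(paste(df$chrom, df$start, df$end, df$strand))
  expect_equal(sort(c(key(sp$a), key(sp$b))), key(tags))
  # determinism
  sp2 <- split_pseudoreplicates(tags, seed = 11)
  expect_equal(sp, sp2)
  # different seed -> different partition
  sp3 <- split_pseudoreplicates(tags, seed = 12)
  expect_false(identical(sp$a, sp3$a))
  # odd n splits 51/50 either way
  odd <- tags[1:101, ]
  so <- split_pseudoreplicates(odd, seed = 5)
  expect_setequal(c(nrow(so$a), nrow(so$b)), c(50, 51))
  expect_error(split_pseudoreplicates(tags[1, , drop = FALSE], 1), ">= 2")
})

test_that("peak matching is one-to-one by best overlap", {
  p1 <- peak_table("chr1", c(100, 500, 900), c(200, 600, 1000),
                   pvalue = c(10, 20, 30))
  # identical sets match fully with equal scores
  m <- match_peaks(p1, p1)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(m$pairs$score1, m$pairs$score2)
  # disjoint sets -> no pairs
  p2 <- peak_table("chr1", c(2000, 3000), c(2100, 3100), pvalue = c(5, 6))
  expect_equal(nrow(match_peaks(p1, p2)$pairs), 0)
  # one peak overlapping two partners: single best-overlap pair
  big <- peak_table("chr1", 100, 650, pvalue = 7)
  m2 <- match_peaks(big, p1)
  expect_equal(nrow(m2$pairs), 1)
  # overlaps tie at 100 bp -> broken toward the higher-scoring partner
  expect_equal(m2$pairs$j, 2)
  expect_equal(m2$unmatched2, c(1, 3))
  expect_warning(match_peaks(p1[0, ], p1), "empty")
})

test_that("IDR fit recovers generating parameters", {
  sc <- simulate_idr_scores(pi = 0.7, rho = 0.9, mu = 2.5, sigma = 1,
                            n = 10000, seed = 42)
  fit <- fit_idr(sc$score1, sc$score2)
  expect_lt(abs(fit$pi - 0.7), 0.05)
  expect_lt(abs(fit$rho - 0.9), 0.05)
  expect_true(fit$converged)
  # global IDR is monotone non-decreasing in rank
  expect_false(is.unsorted(fit$global_idr[order(fit$local_idr)]))
  # local idrs of truly reproducible pairs are lower on average
  expect_lt(mean(fit$local_idr[sc$reproducible]),
            mean(fit$local_idr[!sc$reproducible]))
})

test_that("degenerate and null inputs are handled", {
  # perfectly correlated equal scores -> nearly everything reproducible
  x <- sort(rnorm(200))
  fit <- suppressWarnings(fit_idr(x, x))
  expect_gt(fit$pi, 0.95)
  expect_gt(mean(fit$global_idr <= 0.05), 0.95)
  # independently shuffled pairs -> no reproducible component
  set.seed(19)
  a <- rnorm(5000)
  b <- sample(a)
  fit0 <- fit_idr(a, b)
  expect_lt(fit0$pi, 0.1)
  expect_true(fit0$degenerate)
  expect_equal(sum(fit0$global_idr <= 0.05), 0)
  # simulated pi = 0 behaves the same
  sc0 <- simulate_idr_scores(pi = 0, rho = 0.9, mu = 2.5, sigma = 1,
                             n = 5000, seed = 7)
  expect_lt(fit_idr(sc0$score1, sc0$score2)$pi, 0.1)
  expect_error(fit_idr(rnorm(10), rnorm(10)), "50")
})

test_that("simulate_idr_scores matches its stated model", {
  # pi = 1: single correlated component
  s1 <- simulate_idr_scores(pi = 1, rho = 0.8, mu = 2, sigma = 1,
                            n = 20000, seed = 5)
  expect_lt(abs(cor(s1$score1, s1$score2) - 0.8), 0.02)
  expect_true(all(s1$reproducible))
  # pi = 0: independent standard normals
  s0 <- simulate_idr_scores(pi = 0, rho = 0.8, mu = 2, sigma = 1,
                            n = 20000, seed = 5)
  expect_lt(abs(cor(s0$score1, s0$score2)), 0.02)
  expect_lt(abs(mean(s0$score1)), 0.02)
})

test_that("consistent-peak selection behaves on identical replicates", {
  sim <- simulate_library(sim_config(seed = 8, n_fragments = 30000,
                                     n_genes = 60,
                                     chrom_lengths = c(chr1 = 5e5,
                                                       chr2 = 5e5)))
  dd <- deduplicate(filter_tags(sim$tags, filter_config(),
                                sim$chrom_sizes)$tags)$tags
  pk <- call_peaks(dd, sim$chrom_sizes)
  pooled_tags <- rbind(dd, dd)
  pooled <- call_peaks(pooled_tags, sim$chrom_sizes)
  res <- consistent_peaks(list(pk, pk), pooled, list(dd, dd),
                          sim$chrom_sizes, seed = 4)
  # replicate 2 = copy of replicate 1: all true-rep pairs reproducible,
  # rescue ratio within the conventional [0.5, 2] band, final ~ rep set
  expect_equal(res$n_t, nrow(pk))
  expect_gte(res$rescue_ratio, 0.5)
  expect_lte(res$rescue_ratio, 2)
  expect_gte(nrow(res$peaks), 0.85 * nrow(pk))
  # final peaks are the top pooled peaks: all from the pooled set
  expect_true(all(res$peaks$name %in% pooled$name))
  # lowering a cutoff never increases the passing count
  mp <- match_peaks(pk, pk)
  fit <- suppressWarnings(fit_idr(mp$pairs$score1, mp$pairs$score2))
  expect_lte(sum(fit$global_idr <= 0.01), sum(fit$global_idr <= 0.05))
})
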