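make_peaks_at <- function(summits, chrom = "chr1") {
  peak_table(chrom, summits - 50, summits + 50, pvalue = 1, summit = 50)
}

test_that("promoter window boundaries are inclusive in gene orientation", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                      end = 18000, strand = "+", tss = 10000, tes = 17999,
                      stringsAsFactors = FALSE)
  ann <- classify_peaks(make_peaks_at(c(6000, 5999, 11500, 11501, 17999,
                                        18000)), genes)
  expect_equal(ann$category,
               c("promoter",               # TSS - 4000, inclusive edge
                 "intergenic_upstream",    # one bp beyond
                 "promoter",               # TSS + 1500, inclusive edge
                 "genebody",               # one bp past the promoter limb
                 "genebody",               # last base of the span
                 "intergenic_downstream")) # past the TES
  expect_equal(ann$distance_to_tss[1:2], c(-4000, -4001))
})

test_that("minus-strand promoter is mirrored (upstream is rightward)", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 8000,
                      end = 10001, strand = "-", tss = 10000, tes = 8000,
                      stringsAsFactors = FALSE)
  ann <- classify_peaks(make_peaks_at(c(11500, 14000, 14001, 9000, 8499,
                                        7999)), genes)
  expect_equal(ann$category,
               c("promoter",               # 1500 bp rightward = upstream
                 "promoter",               # 4000 bp rightward edge
                 "intergenic_upstream",    # 4001 bp rightward
                 "promoter",               # d = +1000: promoter precedence
                 "genebody",               # d = +1501, inside span
                 "intergenic_downstream")) # leftward of the TES
  expect_equal(ann$distance_to_tss, c(-1500, -4000, -4001, 1000, 1501,
                                      2001))
})

test_that("boundary sweep changes category exactly at the declared edges", {
  u <- 4000; d <- 1500
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 20000,
                      end = 30000, strand = "+", tss = 20000, tes = 29999,
                      stringsAsFactors = FALSE)
  sweep <- (genes$tss - u - 2):(genes$tes + 2)
  pk <- peak_table("chr1", sweep, sweep + 100, pvalue = 1, summit = 0)
  ann <- classify_peaks(pk, genes)
  changes <- sweep[which(ann$category[-1] != ann$category[-length(sweep)]) + 1]
  expect_equal(changes, c(genes$tss - u,          # -> promoter
                          genes$tss + d + 1,      # -> genebody
                          genes$tes + 1))         # -> intergenic_downstream
})

test_that("strand mirroring leaves every category invariant", {
  L <- 50000
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 20000,
                      end = 26000, strand = "+", tss = 20000, tes = 25999,
                      stringsAsFactors = FALSE)
  set.seed(2)
  summits <- sample(100:(L - 200), 300)
  ann <- classify_peaks(make_peaks_at(summits), genes)
  # mirror: x -> L - 1 - x, flip strand
  m_genes <- data.frame(gene_id = "g1", chrom = "chr1",
                        start = L - genes$end, end = L - genes$start,
                        strand = "-", tss = L - 1 - genes$tss,
                        tes = L - 1 - genes$tes, stringsAsFactors = FALSE)
  m_ann <- classify_peaks(make_peaks_at(L - 1 - summits), m_genes)
  expect_equal(m_ann$category, ann$category)
  expect_equal(m_ann$distance_to_tss, ann$distance_to_tss)
})

test_that("nearest gene is chosen by summit-TSS distance with id tie-break", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      start = c(1000, 9000), end = c(3000, 11000),
                      strand = "+", tss = c(1000, 9000),
                      tes = c(2999, 10999), stringsAsFactors = FALSE)
  ann <- classify_peaks(make_peaks_at(c(2000, 5000, 8000)), genes)
  expect_equal(ann$gene_id, c("gB", "gA", "gA"))   # 5000 ties -> gA < gB
  # summit on a chromosome with no gene -> unassigned
  ann2 <- classify_peaks(make_peaks_at(500, chrom = "chr9"), genes)
  expect_equal(ann2$category, "unassigned")
})

test_that("accessibility-related gene labelling counts promoter summits", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(10000, 50000), end = c(15000, 56000),
                      strand = c("+", "-"), tss = c(10000, 55999),
                      tes = c(14999, 50000), stringsAsFactors = FALSE)
  pk <- make_peaks_at(c(9000, 9500, 11000, 58000, 30000))
  gr <- accessibility_related_genes(pk, genes)
  expect_equal(gr$n_promoter_peaks, c(3, 1))
  expect_true(all(gr$related))
  # no peaks -> empty label set
  gr0 <- accessibility_related_genes(pk[0, ], genes)
  expect_equal(sum(gr0$related), 0)
})

test_that("category proportions sum to one and report unassigned", {
  ann <- data.frame(category = c("promoter", "promoter", "genebody",
                                 "intergenic_upstream", "unassigned"))
  cp <- category_proportions(ann)
  expect_equal(sum(cp$proportions), 1, tolerance = 1e-12)
  expect_equal(unname(cp$proportions["promoter"]), 0.5)
  expect_equal(unname(cp$proportions["intergenic_downstream"]), 0)
  expect_equal(cp$n_unassigned, 1)
  expect_error(category_proportions(ann[0, , drop = FALSE]), "1")
})

test_that("expression join groups by peak count with increasing medians", {
  gene_peaks <- data.frame(gene_id = sprintf("g%02d", 1:40),
                           n_promoter_peaks = rep(c(0, 1, 2, 4), each = 10),
                           related = rep(c(FALSE, TRUE, TRUE, TRUE),
                                         each = 10))
  set.seed(3)
  expr <- data.frame(gene_id = gene_peaks$gene_id,
                     tpm = exp(gene_peaks$n_promoter_peaks +
                                 rnorm(40, 0, 0.1)))
  je <- join_expression(gene_peaks, expr)
  expect_equal(nrow(je$joined), 40)
  expect_equal(je$summary$group, c("0", "1", "2", ">=3"))
  expect_true(all(diff(je$summary$median) > 0))
  # disjoint ids -> empty join with warning
  expr2 <- data.frame(gene_id = paste0("x", 1:40), tpm = 1)
  expect_warning(je2 <- join_expression(gene_peaks, expr2), "50%")
  expect_equal(nrow(je2$joined), 0)
})
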