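make_genes <- function(lay, starts, ends, ids, strand = "+") {
  g <- bed_ranges(rep("chr1", length(starts)), starts, ends, lay,
                  strand = rep_len(strand, length(starts)))
  S4Vectors::mcols(g)$gene_id <- ids
  g
}

test_that("genes split into balanced quantiles by expression rank", {
  lay <- genome_layout(c(chr1 = 100000))
  g <- make_genes(lay, seq(0, 90000, by = 10000), seq(2000, 92000, by = 10000),
                  sprintf("g%02d", 1:10))
  expr <- stats::setNames(1:10, g$gene_id)
  cats <- assign_expression_categories(g, expr, 5, lay)
  expect_equal(unname(table(cats$assignment$category)), rep(2L, 5),
               ignore_attr = TRUE)
  top <- cats$assignment$gene_id[cats$assignment$category == 5]
  expect_setequal(top, c("g09", "g10"))
  # all-equal expression still balances via the gene-id tie-break
  cats2 <- assign_expression_categories(g, stats::setNames(rep(3, 10), g$gene_id),
                                        5, lay)
  expect_equal(unname(table(cats2$assignment$category)), rep(2L, 5),
               ignore_attr = TRUE)
  expect_equal(cats2$assignment$category[order(cats2$assignment$gene_id)],
               rep(1:5, each = 2))
  expect_error(assign_expression_categories(g, expr, 11, lay), "fewer genes")
})

test_that("territory lengths are per-base unions, blacklist removed", {
  lay <- genome_layout(c(chr1 = 100000))
  # two overlapping genes in the same category
  g <- make_genes(lay, c(1000, 1500, 50000, 70000), c(2000, 2600, 51000, 71000),
                  c("a", "b", "c", "d"))
  expr <- c(a = 1, b = 2, c = 10, d = 20)
  cats <- assign_expression_categories(g, expr, 2, lay)
  expect_equal(cats$territory_length[["1"]], 1600)  # union of 1000-2000,1500-2600
  expect_equal(cats$territory_length[["2"]], 2000)
  expect_equal(cats$territory_length[["intergenic"]], 100000 - 1600 - 2000)
  # blacklist subtracted from both gene and intergenic territories
  bl <- bed_ranges("chr1", c(1500, 60000), c(1600, 61000), lay)
  catsb <- assign_expression_categories(g, expr, 2, lay, blacklist = bl)
  expect_equal(catsb$territory_length[["1"]], 1500)
  expect_equal(catsb$territory_length[["intergenic"]], 100000 - 1600 - 2000 - 1000)
})

test_that("density follows the closed-form counts, SE and conservation", {
  lay <- genome_layout(c(chr1 = 100000))
  g <- make_genes(lay, c(10000, 40000), c(20000, 50000), c("lo", "hi"))
  cats <- assign_expression_categories(g, c(lo = 1, hi = 9), 2, lay)
  # 100 peaks: 25 centers inside the "hi" territory (10 kb), 75 intergenic
  s <- c(seq(40100, 44900, length.out = 25), seq(60000, 95000, length.out = 75))
  peaks <- bed_ranges(rep("chr1", 100), round(s), round(s) + 100, lay)
  d <- peak_density_by_category(peaks, cats, "midpoint")
  expect_equal(sum(d$peak_count), d$total_peaks[1])  # exact conservation
  hi <- d[d$category == "2", ]
  expect_equal(hi$peak_count, 25)
  p_hat <- 0.25
  expect_equal(hi$density, 25 / 10000)
  expect_equal(hi$relative_density, 25 / 10000 / 100)
  expect_equal(hi$se_relative, sqrt(p_hat * 0.75 / 100) / 10000, tolerance = 1e-12)
})

test_that("peaks in the blacklist are excluded from N and counts", {
  lay <- genome_layout(c(chr1 = 100000))
  g <- make_genes(lay, 10000, 20000, "g1")
  bl <- bed_ranges("chr1", 50000, 60000, lay)
  cats <- assign_expression_categories(g, c(g1 = 5), 1, lay, blacklist = bl)
  pk <- bed_ranges(rep("chr1", 3), c(12000, 55000, 80000),
                   c(12100, 55100, 80100), lay)
  d <- peak_density_by_category(pk, cats, "midpoint")
  expect_equal(d$total_peaks[1], 2L)  # blacklisted peak dropped entirely
  expect_equal(sum(d$peak_count), 2L)
  # all peaks in blacklist is a degenerate input
  pk_bl <- bed_ranges("chr1", 55000, 55100, lay)
  expect_error(peak_density_by_category(pk_bl, cats), "no peaks")
})

test_that("any_overlap mode can multi-count boundary peaks", {
  lay <- genome_layout(c(chr1 = 100000))
  g <- make_genes(lay, c(10000, 20000), c(20000, 30000), c("lo", "hi"))
  cats <- assign_expression_categories(g, c(lo = 1, hi = 9), 2, lay)
  pk <- bed_ranges("chr1", 19950, 20050, lay)  # spans both genes
  d_any <- peak_density_by_category(pk, cats, "any_overlap")
  expect_equal(sum(d_any$peak_count), 2L)  # counted in both categories
  d_mid <- peak_density_by_category(pk, cats, "midpoint")
  expect_equal(sum(d_mid$peak_count), 1L)
})

test_that("zero-length territory reports NA density, not zero", {
  lay <- genome_layout(c(chr1 = 100000))
  g <- make_genes(lay, c(0, 50000), c(40000, 90000), c("a", "b"))
  bl <- bed_ranges("chr1", 0, 40000, lay)  # erases gene a's territory
  cats <- assign_expression_categories(g, c(a = 1, b = 9), 2, lay, blacklist = bl)
  pk <- bed_ranges("chr1", 60000, 60100, lay)
  d <- peak_density_by_category(pk, cats)
  expect_true(is.na(d$density[d$category == "1"]))
  expect_false(is.na(d$density[d$category == "2"]))
})

test_that("uniform peaks give equal relative densities across categories", {
  cfg <- small_config(seed = 31, n_hotspots = 5000)
  ann <- simulate_annotation(cfg)
  hs <- simulate_hotspots(cfg, ann)
  cats <- assign_expression_categories(ann$genes, ann$expression, 5,
                                       ann$layout, ann$blacklist)
  d <- peak_density_by_category(hs$peaks, cats)
  rel <- d$relative_density / mean(d$relative_density)
  # no planting: every category within sampling noise of the common mean
  expect_true(all(abs(rel - 1) < 0.35))
})
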