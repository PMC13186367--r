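fam_gr <- function(lay, chrom, starts, ends, family) {
  gr <- bed_ranges(chrom, starts, ends, lay)
  S4Vectors::mcols(gr)$family <- rep_len(family, length(gr))
  gr
}

test_that("family overlap counting handles saturation and boundaries", {
  lay <- genome_layout(c(chr1 = 100000))
  peaks <- bed_ranges(rep("chr1", 10), seq(10000, 55000, by = 5000),
                      seq(10000, 55000, by = 5000) + 400, lay)
  everywhere <- fam_gr(lay, "chr1", 0, 100000, "ALL")
  fc <- family_overlap_counts(peaks, everywhere, lay)
  expect_equal(fc$pct, 100)
  # window (350,550) just reaches an element starting at 540
  pk <- bed_ranges("chr1", 400, 500, lay)
  near <- fam_gr(lay, "chr1", 540, 600, "L1")
  expect_equal(family_overlap_counts(pk, near, lay, halfwidth = 100)$count, 1L)
  far <- fam_gr(lay, "chr1", 550, 600, "L1")  # window is [350, 550) half-open
  expect_equal(family_overlap_counts(pk, far, lay, halfwidth = 100)$count, 0L)
  expect_error(family_overlap_counts(GRanges(), near, lay), "empty")
})

test_that("family counts equal a brute-force window scan on random toys", {
  lay <- genome_layout(c(chr1 = 60000, chr2 = 40000))
  set.seed(404)
  for (rep in 1:5) {
    peaks <- random_bed(300, lay, max_width = 600)
    reps <- random_bed(240, lay, max_width = 400)
    S4Vectors::mcols(reps)$family <- sample(c("L1", "MIR", "MaLR"), 240,
                                            replace = TRUE)
    fc <- family_overlap_counts(peaks, reps, lay, halfwidth = 100)
    win <- window_around_center(peaks, 100, lay)
    for (f in fc$family) {
      bf <- sum(brute_force_hits(win, reps[reps$family == f]))
      expect_equal(fc$count[fc$family == f], bf)
    }
  }
})

test_that("multi-family counting is superadditive over the union", {
  lay <- genome_layout(c(chr1 = 60000))
  set.seed(405)
  peaks <- random_bed(200, lay, max_width = 500)
  reps <- random_bed(150, lay, max_width = 300)
  S4Vectors::mcols(reps)$family <- sample(c("A", "B"), 150, replace = TRUE)
  fc <- family_overlap_counts(peaks, reps, lay)
  union_fam <- reps
  S4Vectors::mcols(union_fam)$family <- "U"
  fu <- family_overlap_counts(peaks, union_fam, lay)
  expect_gte(sum(fc$count), fu$count)
})

test_that("center-distance mode implements the strict distance rule", {
  lay <- genome_layout(c(chr1 = 10000))
  pk <- bed_ranges("chr1", 1000, 1100, lay)  # center at 1050
  el <- fam_gr(lay, "chr1", 1249, 1400, "F")  # distance 199 < 200
  expect_equal(family_overlap_counts(pk, el, lay, mode = "center_distance",
                                     max_dist = 200)$count, 1L)
  el2 <- fam_gr(lay, "chr1", 1250, 1400, "F")  # distance exactly 200
  expect_equal(family_overlap_counts(pk, el2, lay, mode = "center_distance",
                                     max_dist = 200)$count, 0L)
})

test_that("enrichment on saturating repeats is NS with ratio 1", {
  lay <- genome_layout(c(chr1 = 50000))
  mask <- build_callable_mask(lay)
  everywhere <- fam_gr(lay, "chr1", 0, 50000, "ALL")
  set.seed(1)
  peaks <- random_bed(100, lay, max_width = 300)
  res <- enrichment_test(peaks, everywhere, mask, lay, n_permutations = 10,
                         seed = 3)
  expect_equal(res$summary$observed_count, 100L)
  expect_equal(res$summary$ratio, 1)
  expect_equal(res$summary$call, "NS")
})

test_that("null counts equal the public shuffle-then-count composition", {
  cfg <- small_config(seed = 17)
  ann <- simulate_annotation(cfg)
  hs <- simulate_hotspots(cfg, ann)
  res <- enrichment_test(hs$peaks, ann$repeats, hs$mask, ann$layout,
                         n_permutations = 4, seed = 90)
  for (i in 1:4) {
    byhand <- family_overlap_counts(
      shuffle_peaks(hs$peaks, hs$mask, 90 + i, ann$layout),
      ann$repeats, ann$layout, halfwidth = 100)
    expect_equal(unname(res$null_counts[byhand$family, i]), byhand$count)
  }
})

test_that("peaks outside the callable mask are refused", {
  lay <- genome_layout(c(chr1 = 50000))
  mask <- build_callable_mask(lay, blacklist = bed_ranges("chr1", 0, 10000, lay))
  bad <- bed_ranges("chr1", 5000, 5200, lay)
  reps <- fam_gr(lay, "chr1", 20000, 21000, "L1")
  expect_error(enrichment_test(bad, reps, mask, lay), "not contained")
  expect_error(enrichment_test(bed_ranges("chr1", 20000, 20100, lay), reps,
                               mask, lay, n_permutations = 0), "n_permutations")
})

test_that("a never-hit family with observed hits reports an infinite ratio", {
  lay <- genome_layout(c(chr1 = 100000))
  # repeats confined to a region the mask excludes from shuffling
  mask <- build_callable_mask(lay, blacklist = bed_ranges("chr1", 0, 50000, lay))
  reps <- fam_gr(lay, "chr1", c(60000, 10000), c(60400, 10400), c("IN", "OUT"))
  peaks <- bed_ranges(rep("chr1", 5), seq(59900, 60300, by = 100),
                      seq(59900, 60300, by = 100) + 50, lay)
  res <- enrichment_test(peaks, reps, mask, lay, n_permutations = 15, seed = 8)
  out_row <- res$summary[res$summary$family == "OUT", ]
  expect_equal(out_row$observed_count, 0L)
  expect_true(is.na(out_row$ratio))  # 0 observed over 0 expected
  # shrink the mask so the IN family is reachable but rare, observed high
  in_row <- res$summary[res$summary$family == "IN", ]
  expect_gte(in_row$ratio, 1)
})

test_that("the range rule calls planted enrichment on a small toy", {
  cfg <- small_config(seed = 19, n_hotspots = 800,
                      planted_family_enrichment = c(MaLR = 4))
  ann <- simulate_annotation(cfg)
  hs <- simulate_hotspots(cfg, ann)
  res <- enrichment_test(hs$peaks, ann$repeats, hs$mask, ann$layout,
                         n_permutations = 40, seed = 77)
  malr <- res$summary[res$summary$family == "MaLR", ]
  expect_equal(malr$call, "enriched")
  expect_gt(malr$ratio, 2)
})
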