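test_that("config validation catches infeasible or nonsensical parameters", {
  expect_error(synthetic_config(blacklist_fraction = 1.2), "fractions")
  expect_error(synthetic_config(blacklist_fraction = 0.5, zero_cov_fraction = 0.45),
               "infeasible")
  expect_error(synthetic_config(planted_family_enrichment = c(L1 = 0)), "> 0")
  expect_error(synthetic_config(n_hotspots = 0), "n_hotspots")
  expect_error(synthetic_config(recmap = list(background_rate = 0.5,
                                              tss_peak_factor = 1,
                                              tss_peak_halfwidth = 100,
                                              genebody_suppression = c(1, 1))),
               "one factor per")
})

test_that("annotation is deterministic in the seed and distinct across seeds", {
  cfg <- small_config(seed = 23)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(granges(a1$genes), granges(a2$genes))
  expect_identical(a1$expression, a2$expression)
  expect_identical(granges(a1$repeats), granges(a2$repeats))
  a3 <- simulate_annotation(small_config(seed = 24))
  expect_false(identical(granges(a1$genes), granges(a3$genes)))
})

test_that("generated annotation honours its structural contracts", {
  cfg <- small_config(seed = 25)
  ann <- simulate_annotation(cfg)
  expect_equal(length(ann$genes), cfg$n_genes)
  # genes are non-overlapping
  expect_equal(length(findOverlaps(ann$genes, drop.self = TRUE)), 0L)
  # realized repeat fraction near target (L1: 15% of the genome)
  genome_bp <- sum(as.numeric(GenomeInfoDb::seqlengths(ann$layout)))
  l1 <- sum(width(reduce(ann$repeats[ann$repeats$family == "L1"]))) / genome_bp
  expect_gt(l1, 0.12)
  expect_lt(l1, 0.18)
  # expression non-negative with the configured silent fraction
  expect_true(all(ann$expression >= 0))
  silent <- mean(ann$expression == 0)
  expect_gt(silent, 0.1)
  expect_lt(silent, 0.3)
  # zero blacklist fraction produces an empty blacklist
  ann0 <- simulate_annotation(small_config(seed = 26, blacklist_fraction = 0))
  expect_length(ann0$blacklist, 0)
})

test_that("hotspots land in the callable mask at the requested count", {
  cfg <- small_config(seed = 27)
  ann <- simulate_annotation(cfg)
  hs <- simulate_hotspots(cfg, ann)
  expect_length(hs$peaks, cfg$n_hotspots)
  expect_true(all(countOverlaps(hs$peaks, hs$mask, type = "within") > 0))
  # deterministic
  hs2 <- simulate_hotspots(cfg, ann)
  expect_identical(granges(hs$peaks), granges(hs2$peaks))
})

test_that("uniform hotspot placement matches the mask's spatial law", {
  # no planting: center positions uniform over the mask; compare the
  # realized fraction in each mask half with its capacity share
  cfg <- small_config(seed = 7, n_hotspots = 3000)
  ann <- simulate_annotation(cfg)
  hs <- simulate_hotspots(cfg, ann)
  lens <- GenomeInfoDb::seqlengths(ann$layout)
  on_chr1 <- as.character(seqnames(hs$peaks)) == "chr1"
  cap1 <- sum(width(hs$mask[as.character(seqnames(hs$mask)) == "chr1"]))
  cap <- sum(width(hs$mask))
  expect_equal(mean(on_chr1), cap1 / cap, tolerance = 0.05)
  p <- stats::binom.test(sum(on_chr1), length(hs$peaks), cap1 / cap)$p.value
  expect_gt(p, 0.001)
})

test_that("planted family enrichment is realized at the planted rate", {
  cfg <- small_config(seed = 29, n_hotspots = 2000,
                      planted_family_enrichment = c(MaLR = 3))
  ann <- simulate_annotation(cfg)
  hs <- simulate_hotspots(cfg, ann)
  fc <- family_overlap_counts(hs$peaks, ann$repeats, ann$layout, halfwidth = 100)
  obs_frac <- fc$count[fc$family == "MaLR"] / length(hs$peaks)
  # analytic expectation: q' = f q / (1 - q + f q) with q the zone share
  lidx <- recland:::linear_index(ann$layout)
  zone <- recland:::family_zones(ann$repeats, "MaLR", lidx, halfwidth = 100)$MaLR
  q <- sum(zone$hi - zone$lo + 1) / sum(width(hs$mask))
  expected <- 3 * q / (1 - q + 3 * q)
  expect_equal(obs_frac, expected, tolerance = 0.25)
  expect_gt(obs_frac, 1.8 * q)  # clearly above the uniform rate
})

test_that("the simulated map encodes suppression and TSS elevation exactly", {
  cfg <- small_config(seed = 33)
  ann <- simulate_annotation(cfg)
  rm_ <- simulate_recmap(cfg, ann)
  rmap <- rm_$recmap
  # non-overlapping and covering the genome
  expect_equal(length(findOverlaps(rmap, drop.self = TRUE)), 0L)
  expect_equal(sum(as.numeric(width(rmap))),
               sum(as.numeric(GenomeInfoDb::seqlengths(ann$layout))))
  # class-3 gene bodies away from any TSS zone carry exactly 0.5 x background
  truth <- rm_$truth
  cls <- truth[truth$kind == "gene_class", ]
  g3 <- ann$genes[ann$genes$gene_id %in% cls$name[cls$value == 3]]
  tss_zone <- reduce(GRanges(seqnames(ann$genes),
                             IRanges(pmax(ann$genes$tss + 1 - 1000, 1),
                                     ann$genes$tss + 1 + 1000)))
  body <- GenomicRanges::setdiff(reduce(granges(g3)), tss_zone,
                                 ignore.strand = TRUE)
  hit <- rmap[countOverlaps(rmap, body, type = "within") > 0]
  expect_true(all(abs(hit$rate - 0.5 * 0.5) < 1e-12))
  # TSS zones outside gene bodies carry exactly factor x background
  promoter_only <- GenomicRanges::setdiff(tss_zone, reduce(granges(ann$genes)),
                                          ignore.strand = TRUE)
  hit2 <- rmap[countOverlaps(rmap, promoter_only, type = "within") > 0]
  expect_true(all(abs(hit2$rate - 10 * 0.5) < 1e-12))
})

test_that("a written dataset is valid input for every reader", {
  cfg <- small_config(seed = 37)
  outdir <- withr::local_tempdir()
  paths <- simulate_dataset(cfg, outdir)
  expect_true(all(file.exists(paths)))
  lay <- read_genome_layout(paths["genome"])
  expect_equal(unname(GenomeInfoDb::seqlengths(lay)),
               rep(cfg$chromosome_length, cfg$n_chromosomes))
  genes <- read_genes_gtf(paths["genes"], lay)
  expect_equal(length(genes), cfg$n_genes)
  expr <- read_expression_tsv(paths["expression"])
  expect_setequal(names(expr), genes$gene_id)
  reps <- read_repeatmasker(paths["repeats"], lay,
                            families = names(cfg$repeat_families))
  expect_gt(length(reps), 0)
  expect_equal(attr(reps, "n_dropped"), 0L)
  hs <- read_intervals(paths["hotspots"], lay, "BED3")
  expect_length(hs, cfg$n_hotspots)
  rmap <- read_recmap_bedgraph(paths["recmap"], lay)
  expect_gt(length(rmap), 0)
  truth <- read_table_tsv(paths["truth"])
  expect_true(all(c("kind", "name", "value") %in% names(truth)))
  # byte-identical regeneration under the same seed
  outdir2 <- withr::local_tempdir()
  simulate_dataset(cfg, outdir2)
  for (nm in names(paths)) {
    expect_identical(readLines(paths[[nm]]),
                     readLines(file.path(outdir2, basename(paths[[nm]]))),
                     info = nm)
  }
})
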