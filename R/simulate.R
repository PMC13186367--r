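#' Configuration for the synthetic-data generator
#'
#' Builds and validates the parameter set describing a toy genome with the
#' statistical structure the analysis stages assume: a multi-chromosome
#' layout, non-overlapping gene models with log-normal lengths and
#' expression, repeat families with target genomic fractions, blacklist and
#' zero-coverage masks, a hotspot set with optional planted per-family and
#' per-expression-category placement enrichment, and a piecewise-constant
#' recombination map with a TSS elevation and expression-dependent
#' gene-body suppression.
#'
#' Length and expression laws are log-normal `(meanlog, sdlog)` — simple
#' heavy-tailed stand-ins adequate for the rank/quantile operations the
#' pipeline performs. All placement factors are multiplicative on an
#' otherwise uniform placement density, so a planted factor is exactly a
#' density ratio and can be recovered analytically.
#'
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param n_chromosomes,chromosome_length Genome shape (default 4 x 5 Mb).
#' @param n_genes Number of genes (default 800).
#' @param gene_length_law,expression_law,hotspot_width_law Named numeric
#'   vectors `c(meanlog=, sdlog=)`.
#' @param zero_expression_fraction Fraction of genes with expression forced
#'   to zero (silent in the profiled cell stage), default 0.2.
#' @param repeat_families Named list; each entry
#'   `list(fraction=, meanlog=, sdlog=)` gives the target genomic fraction
#'   and the element-length law of one family.
#' @param blacklist_fraction,zero_cov_fraction Target genomic fractions of
#'   the blacklist and of zero-coverage runs.
#' @param min_zero_run Zero-coverage runs longer than this are excluded
#'   from the callable mask (bp, default 1000).
#' @param n_hotspots Number of hotspots to place (default 2000).
#' @param planted_family_enrichment Named numeric vector: multiplicative
#'   placement factor for hotspot centers within `halfwidth` bp of elements
#'   of that family (default: none, i.e. all 1).
#' @param planted_expression_density Numeric vector of length
#'   `density_quantiles`: placement factor for hotspot centers inside gene
#'   territories of each expression quantile (default all 1; intergenic is
#'   always 1).
#' @param halfwidth Center-window half-width used both for planting and in
#'   the enrichment stage (bp, default 100).
#' @param density_quantiles,profile_classes Number of expression quantiles
#'   for the density stage (5) and of classes for the recombination map (3).
#' @param recmap List: `background_rate` (cM/Mb), `tss_peak_factor`,
#'   `tss_peak_halfwidth` (bp), `genebody_suppression` (numeric vector of
#'   length `profile_classes`, factor applied inside gene bodies of each
#'   expression class, class 1 lowest).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    n_chromosomes = 4,
    chromosome_length = 5e6,
    n_genes = 800,
    gene_length_law = c(meanlog = log(8000), sdlog = 0.7),
    expression_law = c(meanlog = 1, sdlog = 1.5),
    zero_expression_fraction = 0.2,
    repeat_families = list(
      L1 = list(fraction = 0.15, meanlog = log(600), sdlog = 0.8),
      ERVK = list(fraction = 0.04, meanlog = log(400), sdlog = 0.7),
      MaLR = list(fraction = 0.01, meanlog = log(350), sdlog = 0.6),
      MIR = list(fraction = 0.025, meanlog = log(200), sdlog = 0.5),
      Simple_repeat = list(fraction = 0.02, meanlog = log(100), sdlog = 0.6)
    ),
    blacklist_fraction = 0.02,
    zero_cov_fraction = 0.05,
    min_zero_run = 1000,
    n_hotspots = 2000,
    hotspot_width_law = c(meanlog = log(300), sdlog = 0.3),
    planted_family_enrichment = NULL,
    planted_expression_density = NULL,
    halfwidth = 100,
    density_quantiles = 5,
    profile_classes = 3,
    recmap = list(background_rate = 0.5, tss_peak_factor = 10,
                  tss_peak_halfwidth = 1000,
                  genebody_suppression = c(1, 0.8, 0.5))) {
  cfg <- as.list(environment())
  if (is.null(cfg$planted_expression_density)) {
    cfg$planted_expression_density <- rep(1, density_quantiles)
  }
  fracs <- c(blacklist_fraction, zero_cov_fraction,
             vapply(repeat_families, function(f) f$fraction, 0))
  if (any(fracs < 0 | fracs > 1)) stop("all genomic fractions must lie in [0, 1]")
  if (sum(fracs) >= 0.9) {
    stop("total annotated fraction ", round(sum(fracs), 2),
         " is infeasible; keep it below 0.9")
  }
  if (!is.null(cfg$planted_family_enrichment) &&
      any(cfg$planted_family_enrichment <= 0)) {
    stop("planted enrichment factors must be > 0")
  }
  if (any(cfg$planted_expression_density <= 0)) {
    stop("planted density factors must be > 0")
  }
  if (length(cfg$recmap$genebody_suppression) != profile_classes) {
    stop("genebody_suppression must have one factor per expression class")
  }
  if (any(unlist(cfg$recmap[c("background_rate", "tss_peak_factor")]) < 0) ||
      any(cfg$recmap$genebody_suppression <= 0)) {
    stop("recombination-map factors must be positive")
  }
  if (n_hotspots < 1) stop("n_hotspots must be >= 1")
  structure(cfg, class = "synthetic_config")
}

# draw interval lengths from a log-normal law until their sum reaches
# target_bp (RNG must be active)
draw_lengths_to_target <- function(target_bp, meanlog, sdlog, min_len = 20) {
  if (target_bp <= 0) return(integer())
  mean_len <- exp(meanlog + sdlog^2 / 2)
  out <- integer()
  while (sum(out) < target_bp) {
    k <- max(10L, ceiling((target_bp - sum(out)) / mean_len * 1.2))
    out <- c(out, pmax(as.integer(round(stats::rlnorm(k, meanlog, sdlog))), min_len))
  }
  cum <- cumsum(out)
  out[seq_len(which(cum >= target_bp)[1L])]
}

# place intervals of the given widths uniformly (overlap allowed) on a layout
place_anywhere <- function(widths, layout) {
  lens <- layout_lengths(layout)
  if (!length(widths)) {
    gr <- GenomicRanges::GRanges()
    gr <- set_layout(gr, layout)
    return(gr)
  }
  widths <- pmin(widths, min(lens))
  chr <- sample(names(lens), length(widths), replace = TRUE, prob = lens)
  start <- floor(stats::runif(length(widths)) * (lens[chr] - widths + 1)) + 1
  gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(as.integer(start),
                                                     width = as.integer(widths)))
  gr <- set_layout(gr, layout)
  gr
}

# uniform placement over all legal (whole-segment-contained) positions of
# the mask, one placement per width (RNG must be active)
place_in_mask <- function(widths, mask, layout) {
  lidx <- linear_index(layout)
  sampler <- mask_sampler(mask, lidx)
  lin <- draw_placements(widths, sampler)
  pos <- delinearize(lin, lidx)
  gr <- GenomicRanges::GRanges(pos$chrom,
                               IRanges::IRanges(as.integer(pos$pos0) + 1L,
                                                width = widths))
  set_layout(gr, layout)
}

#' Simulate a genome annotation
#'
#' Generates the layout, non-overlapping gene models with strand and
#' log-normal expression, repeat elements per family at their target
#' genomic fractions (free to overlap genes and each other), and blacklist
#' and zero-coverage masks. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list `layout`, `genes` (`GRanges` with `gene_id`, `tss`,
#'   `tes`), `expression` (named numeric), `repeats` (`GRanges` with
#'   `family`), `blacklist`, `zero_cov` (`GRanges`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lens <- rep(config$chromosome_length, config$n_chromosomes)
  names(lens) <- paste0("chr", seq_len(config$n_chromosomes))
  layout <- genome_layout(lens)
  genome_bp <- sum(lens)
  withr::with_seed(config$seed, {
    # genes: rejection sampling until non-overlapping
    glaw <- config$gene_length_law
    gw <- pmax(as.integer(round(stats::rlnorm(config$n_genes, glaw["meanlog"],
                                              glaw["sdlog"]))), 200L)
    gw <- pmin(gw, floor(config$chromosome_length / 10))
    gw <- sort(gw, decreasing = TRUE)  # long genes first, while gaps are large
    accepted <- GenomicRanges::GRanges()
    widths_left <- gw
    tries <- 0L
    while (length(widths_left) && tries < 200L) {
      tries <- tries + 1L
      widths_left <- sort(widths_left, decreasing = TRUE)
      cand <- place_anywhere(widths_left, layout)
      ok <- GenomicRanges::countOverlaps(cand, accepted) == 0L
      cand <- cand[ok]
      widths_left <- widths_left[!ok]
      # also drop candidates overlapping an earlier candidate of this batch
      if (length(cand) > 1L) {
        self <- GenomicRanges::findOverlaps(cand, drop.self = TRUE)
        clash <- S4Vectors::queryHits(self) > S4Vectors::subjectHits(self)
        drop <- unique(S4Vectors::queryHits(self)[clash])
        if (length(drop)) {
          widths_left <- c(widths_left, GenomicRanges::width(cand)[drop])
          cand <- cand[-drop]
        }
      }
      accepted <- c(accepted, cand)
    }
    if (length(widths_left)) {
      stop("could not pack ", length(widths_left),
           " gene(s) without overlap; lower n_genes or gene lengths")
    }
    genes <- GenomicRanges::sort(accepted)
    GenomicRanges::strand(genes) <- sample(c("+", "-"), length(genes),
                                           replace = TRUE)
    S4Vectors::mcols(genes)$gene_id <- sprintf("g%04d", seq_along(genes))
    genes <- gene_tss_tes(genes)
    # expression: log-normal with a silent fraction
    elaw <- config$expression_law
    expr <- stats::rlnorm(length(genes), elaw["meanlog"], elaw["sdlog"])
    silent <- stats::runif(length(genes)) < config$zero_expression_fraction
    expr[silent] <- 0
    expression <- stats::setNames(expr, genes$gene_id)
    # repeats per family
    rep_list <- lapply(names(config$repeat_families), function(fam) {
      p <- config$repeat_families[[fam]]
      w <- draw_lengths_to_target(p$fraction * genome_bp, p$meanlog, p$sdlog)
      gr <- place_anywhere(w, layout)
      S4Vectors::mcols(gr)$family <- rep(fam, length(gr))
      gr
    })
    repeats <- GenomicRanges::sort(do.call(c, rep_list))
    # masks
    blacklist <- GenomicRanges::sort(place_anywhere(
      draw_lengths_to_target(config$blacklist_fraction * genome_bp,
                             log(20000), 0.5), layout))
    zero_cov <- GenomicRanges::sort(place_anywhere(
      draw_lengths_to_target(config$zero_cov_fraction * genome_bp,
                             log(1500), 0.8), layout))
  })
  list(layout = layout, genes = genes, expression = expression,
       repeats = repeats, blacklist = blacklist, zero_cov = zero_cov)
}

# multiplicative placement factor at each 0-based center position
placement_factor <- function(center_chr, center0, zones) {
  f <- rep(1, length(center0))
  if (!length(zones)) return(f)
  pts <- GenomicRanges::GRanges(center_chr, IRanges::IRanges(center0 + 1L, width = 1L))
  for (z in zones) {
    hit <- GenomicRanges::countOverlaps(pts, z$gr, ignore.strand = TRUE) > 0L
    f[hit] <- f[hit] * z$factor
  }
  f
}

#' Simulate a hotspot set with planted enrichment
#'
#' Places `n_hotspots` hotspots in the callable genome (genome minus
#' blacklist minus long zero-coverage runs). The placement density is
#' uniform over legal placements, multiplied by the planted per-family
#' factor wherever the hotspot center falls within `halfwidth` bp of an
#' element of that family, and by the planted per-expression-category
#' factor wherever the center falls inside a gene territory of that
#' category. Sampling is by thinning (max-factor rejection), so a planted
#' factor is exactly the ratio of placement densities in and out of its
#' zone.
#'
#' @param config A [synthetic_config()].
#' @param annotation Result of [simulate_annotation()].
#' @return List `peaks` (labelled `GRanges`), `mask` (callable mask) and
#'   `truth` (data.frame of planted parameters and realized zone fractions).
#' @export
simulate_hotspots <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"))
  layout <- annotation$layout
  mask <- build_callable_mask(layout, annotation$blacklist,
                              annotation$zero_cov, config$min_zero_run)
  zones <- list()
  fam_factors <- config$planted_family_enrichment
  if (!is.null(fam_factors)) {
    for (fam in names(fam_factors)) {
      if (fam_factors[[fam]] == 1) next
      el <- annotation$repeats[annotation$repeats$family == fam]
      if (!length(el)) stop("planted family not simulated: ", fam)
      zone <- suppressWarnings(GenomicRanges::reduce(
        GenomicRanges::resize(GenomicRanges::granges(el),
                              GenomicRanges::width(el) + 2L * config$halfwidth,
                              fix = "center"),
        ignore.strand = TRUE))
      zone <- GenomicRanges::trim(zone)
      zone <- zone[GenomicRanges::start(zone) >= 1L]
      zones[[length(zones) + 1L]] <- list(gr = zone, factor = fam_factors[[fam]])
    }
  }
  dens_factors <- config$planted_expression_density
  categories <- NULL
  if (any(dens_factors != 1)) {
    categories <- assign_expression_categories(
      annotation$genes, annotation$expression,
      n_quantiles = config$density_quantiles, layout = layout)
    for (k in seq_len(config$density_quantiles)) {
      if (dens_factors[k] == 1) next
      zones[[length(zones) + 1L]] <- list(
        gr = categories$territories[[as.character(k)]],
        factor = dens_factors[k])
    }
  }
  fmax <- prod(vapply(zones, function(z) max(z$factor, 1), 1))
  wlaw <- config$hotspot_width_law
  n <- config$n_hotspots
  peaks <- GenomicRanges::GRanges()
  withr::with_seed(config$seed + 104729L, {  # independent stream from annotation
    it <- 0L
    while (length(peaks) < n && it < 200L) {
      it <- it + 1L
      m <- min(ceiling((n - length(peaks)) * fmax * 1.2) + 10L, 50L * n)
      w <- pmax(as.integer(round(stats::rlnorm(m, wlaw["meanlog"], wlaw["sdlog"]))), 50L)
      w <- pmin(w, max(GenomicRanges::width(mask)))
      cand <- place_in_mask(w, mask, layout)
      c0 <- GenomicRanges::start(cand) - 1L +
        floor(GenomicRanges::width(cand) / 2)
      f <- placement_factor(as.character(GenomicRanges::seqnames(cand)), c0, zones)
      keep <- stats::runif(m) < f / fmax
      peaks <- c(peaks, cand[keep])
    }
  })
  if (length(peaks) < n) {
    stop("hotspot placement did not converge; lower planted factors or n_hotspots")
  }
  peaks <- GenomicRanges::sort(peaks[seq_len(n)])
  S4Vectors::metadata(peaks)$label <- "synthetic_hotspots"
  truth <- data.frame(
    kind = character(), name = character(), value = numeric(),
    stringsAsFactors = FALSE)
  if (!is.null(fam_factors)) {
    truth <- rbind(truth, data.frame(
      kind = "family_enrichment", name = names(fam_factors),
      value = as.numeric(unlist(fam_factors))))
  }
  truth <- rbind(truth, data.frame(
    kind = "expression_density",
    name = as.character(seq_along(dens_factors)),
    value = as.numeric(dens_factors)))
  truth <- rbind(truth, data.frame(
    kind = "meta", name = c("n_hotspots", "halfwidth"),
    value = c(n, config$halfwidth)))
  list(peaks = peaks, mask = mask, truth = truth)
}

#' Simulate a recombination map with TSS elevation and gene-body suppression
#'
#' Builds a piecewise-constant map over the whole genome: the background
#' rate, multiplied by `tss_peak_factor` within `tss_peak_halfwidth` bp of
#' any TSS, and by the class's `genebody_suppression` factor inside gene
#' bodies — classes are equal-sized expression tertiles (by default) over
#' the detectably expressed genes, class 1 lowest. Where gene bodies of
#' different classes overlap a position, the strongest (smallest) factor
#' applies. The map is deterministic given the annotation.
#'
#' @param config A [synthetic_config()].
#' @param annotation Result of [simulate_annotation()].
#' @return List `recmap` (`GRanges` with `rate`) and `truth` (data.frame
#'   with the planted factors and the per-gene class assignment).
#' @export
simulate_recmap <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"))
  layout <- annotation$layout
  genes <- annotation$genes
  expr <- annotation$expression[genes$gene_id]
  keep <- !is.na(expr) & expr > 0
  eg <- genes[keep]
  ee <- expr[keep]
  ncl <- config$profile_classes
  if (length(eg) < ncl) stop("too few expressed genes for ", ncl, " classes")
  o <- order(ee, eg$gene_id)
  cls <- integer(length(eg))
  cls[o] <- floor((seq_along(eg) - 1) * ncl / length(eg)) + 1L
  p <- config$recmap
  lens <- layout_lengths(layout)
  tss_zone <- GenomicRanges::reduce(GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(genes)),
    IRanges::IRanges(pmax(genes$tss + 1L - p$tss_peak_halfwidth, 1L),
                     pmin(genes$tss + 1L + p$tss_peak_halfwidth,
                          lens[as.character(GenomicRanges::seqnames(genes))]))))
  class_terr <- lapply(seq_len(ncl), function(k) {
    GenomicRanges::reduce(GenomicRanges::granges(eg[cls == k]),
                          ignore.strand = TRUE)
  })
  pieces <- GenomicRanges::disjoin(c(genome_ranges(layout),
                                     GenomicRanges::granges(tss_zone),
                                     do.call(c, class_terr)),
                                   ignore.strand = TRUE)
  rate <- rep(p$background_rate, length(pieces))
  in_tss <- GenomicRanges::countOverlaps(pieces, tss_zone) > 0L
  rate[in_tss] <- rate[in_tss] * p$tss_peak_factor
  supp <- rep(1, length(pieces))
  for (k in seq_len(ncl)) {
    hit <- GenomicRanges::countOverlaps(pieces, class_terr[[k]]) > 0L
    supp[hit] <- pmin(supp[hit], p$genebody_suppression[k])
  }
  rate <- rate * supp
  recmap <- GenomicRanges::sort(pieces)
  S4Vectors::mcols(recmap)$rate <- rate[order(pieces)]
  truth <- rbind(
    data.frame(kind = "genebody_suppression",
               name = as.character(seq_len(ncl)),
               value = p$genebody_suppression, stringsAsFactors = FALSE),
    data.frame(kind = "recmap", name = c("background_rate", "tss_peak_factor",
                                         "tss_peak_halfwidth"),
               value = c(p$background_rate, p$tss_peak_factor,
                         p$tss_peak_halfwidth)))
  class_df <- data.frame(kind = "gene_class", name = eg$gene_id,
                         value = cls, stringsAsFactors = FALSE)
  list(recmap = recmap, truth = rbind(truth, class_df))
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_annotation()], [simulate_hotspots()] and
#' [simulate_recmap()] and writes every piece in the interchange format the
#' corresponding reader expects, plus a `truth.tsv` recording the planted
#' parameters.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(config)
  hs <- simulate_hotspots(config, ann)
  rm_ <- simulate_recmap(config, ann)
  paths <- c(
    genome = file.path(outdir, "genome.tsv"),
    genes = file.path(outdir, "genes.gtf"),
    expression = file.path(outdir, "expression.tsv"),
    repeats = file.path(outdir, "repeats_rmsk.tsv"),
    blacklist = file.path(outdir, "blacklist.bed"),
    zero_cov = file.path(outdir, "zerocov.bed"),
    hotspots = file.path(outdir, "hotspots.bed"),
    recmap = file.path(outdir, "recmap.bedgraph"),
    truth = file.path(outdir, "truth.tsv")
  )
  lens <- layout_lengths(ann$layout)
  writeLines(paste(names(lens), format_num(lens), sep = "\t"), paths["genome"])
  write_genes_gtf(ann$genes, paths["genes"])
  write_table(data.frame(gene_id = names(ann$expression),
                         expression = unname(ann$expression)),
              paths["expression"])
  rk <- ann$repeats
  write_table(data.frame(
    genoName = as.character(GenomicRanges::seqnames(rk)),
    genoStart = GenomicRanges::start(rk) - 1L,
    genoEnd = GenomicRanges::end(rk),
    strand = "+",
    repName = paste0(rk$family, "_el"),
    repClass = rk$family,
    repFamily = rk$family), paths["repeats"])
  write_bed(ann$blacklist, paths["blacklist"])
  write_bed(ann$zero_cov, paths["zero_cov"])
  write_bed(hs$peaks, paths["hotspots"])
  write_recmap_bedgraph(rm_$recmap, paths["recmap"])
  write_table(rbind(hs$truth, rm_$truth), paths["truth"])
  invisible(paths)
}
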