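#' Metagene coordinate of genomic positions
#'
#' Assigns each position to its nearest gene (distance to the gene span,
#' zero if inside) and expresses it in the strand-oriented metagene frame:
#' inside a gene the side is the nearer of TSS/TES and the offset is the
#' distance to that end (`>= 0`); outside, the side is the gene end being
#' flanked (upstream of the TSS -> side `TSS`, downstream of the TES ->
#' side `TES`) and the offset is minus the distance to the span. Positions
#' on a chromosome without genes are returned unassigned (`NA` row).
#'
#' Nearest-gene ties are broken by smallest gene id; the TSS wins an exact
#' inside tie between the two ends.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 0-based bp positions, parallel to `chrom`.
#' @param genes `GRanges` gene models with `gene_id`, `tss`, `tes` columns
#'   (as from [read_genes_gtf()]).
#' @param layout Genome layout.
#' @return data.frame with columns `side` ("TSS"/"TES"), `offset` (signed
#'   bp) and `gene_id`, one row per input position.
#' @export
metagene_coordinate <- function(chrom, pos, genes, layout) {
  if (length(chrom) == 1L) chrom <- rep_len(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  genes <- validate_intervals(genes, layout)
  n <- length(pos)
  out <- data.frame(side = rep(NA_character_, n), offset = rep(NA_real_, n),
                    gene_id = rep(NA_character_, n), stringsAsFactors = FALSE)
  if (n == 0L || length(genes) == 0L) return(out)
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  pts <- set_layout(pts, layout)
  hits <- GenomicRanges::distanceToNearest(pts, genes, ignore.strand = TRUE,
                                           select = "all")
  if (length(hits) == 0L) return(out)
  dt <- data.table::data.table(
    q = S4Vectors::queryHits(hits),
    g = S4Vectors::subjectHits(hits),
    d = S4Vectors::mcols(hits)$distance
  )
  dt[, gid := genes$gene_id[g]]
  data.table::setorderv(dt, c("q", "d", "gid"))
  dt <- dt[!duplicated(q)]
  g <- genes[dt$g]
  p0 <- pos[dt$q]
  s0 <- GenomicRanges::start(g) - 1L
  e0 <- GenomicRanges::end(g)          # exclusive
  tss <- g$tss
  tes <- g$tes
  inside <- p0 >= s0 & p0 < e0
  d_tss <- abs(p0 - tss)
  d_tes <- abs(p0 - tes)
  side <- character(nrow(dt))
  offset <- numeric(nrow(dt))
  side[inside] <- ifelse(d_tss[inside] <= d_tes[inside], "TSS", "TES")
  offset[inside] <- pmin(d_tss[inside], d_tes[inside])
  # outside: which end of the span is being flanked depends on strand
  left <- !inside & p0 < s0
  right <- !inside & p0 >= e0
  plus <- as.character(GenomicRanges::strand(g)) == "+"
  side[left] <- ifelse(plus[left], "TSS", "TES")
  side[right] <- ifelse(plus[right], "TES", "TSS")
  offset[left] <- -(s0[left] - p0[left])
  offset[right] <- -(p0[right] - (e0[right] - 1L))
  out$side[dt$q] <- side
  out$offset[dt$q] <- offset
  out$gene_id[dt$q] <- dt$gid
  out
}

#' Recombination-rate profile by distance to TSS/TES and expression class
#'
#' Reproduces a metagene view of a recombination map: only genes with
#' detectable expression (value > 0) are kept and split into `n_classes`
#' equal-sized groups by expression rank (class 1 lowest). The genome is
#' scanned in fixed non-overlapping windows; each window midpoint is placed
#' in the metagene frame of that class's genes only, windows farther than
#' `max_dist` from both ends are dropped, and the map rate is averaged per
#' (class, side, distance bin) weighting each contribution by the map bases
#' covered: `mean_rate = sum(rate * overlap_bp) / sum(overlap_bp)`.
#'
#' @param recmap `GRanges` with `rate` column (cM/Mb).
#' @param genes `GRanges` gene models (`gene_id`, `tss`, `tes`).
#' @param expression Named numeric vector, gene id -> expression.
#' @param layout Genome layout.
#' @param n_classes Number of expression classes (default 3).
#' @param window_width Scan window width in bp (default 1000).
#' @param bin_width Distance-bin width in bp (default 1000).
#' @param max_dist Maximum |distance| retained, bp (default 50000).
#' @return data.frame with columns `expression_class`, `side`, `bin_lo`,
#'   `bin_hi` (offset bin, bp, half-open), `mean_rate`, `covered_bp`.
#' @export
recombination_profile <- function(recmap, genes, expression, layout,
                                  n_classes = 3, window_width = 1000,
                                  bin_width = 1000, max_dist = 50000) {
  if (length(recmap) == 0L) stop("empty recombination map")
  recmap <- validate_intervals(recmap, layout)
  genes <- validate_intervals(genes, layout)
  expr <- expression[genes$gene_id]
  keep <- !is.na(expr) & expr > 0
  genes <- genes[keep]
  expr <- expr[keep]
  if (length(genes) < n_classes) {
    stop("fewer detectably expressed genes (", length(genes),
         ") than classes (", n_classes, ")")
  }
  o <- order(expr, genes$gene_id)
  class_of <- integer(length(genes))
  class_of[o] <- floor((seq_along(genes) - 1) * n_classes / length(genes)) + 1L
  # fixed scan windows tiling every chromosome
  lens <- layout_lengths(layout)
  win <- unlist(GenomicRanges::GRangesList(lapply(names(lens), function(ch) {
    starts <- seq(1L, lens[[ch]], by = window_width)
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      starts, pmin(starts + window_width - 1L, lens[[ch]])))
  })))
  win <- set_layout(win, layout)
  # map coverage per window: sum(rate*bp) and bp
  fo <- GenomicRanges::findOverlaps(win, recmap)
  ov_w <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(win)[S4Vectors::queryHits(fo)],
    IRanges::ranges(recmap)[S4Vectors::subjectHits(fo)]))
  cov <- data.table::data.table(
    w = S4Vectors::queryHits(fo),
    num = recmap$rate[S4Vectors::subjectHits(fo)] * ov_w,
    den = ov_w)
  cov <- cov[, list(num = sum(num), den = sum(den)), by = "w"]
  mid0 <- GenomicRanges::start(win) - 1L + floor(window_width / 2)
  mid0 <- pmin(mid0, GenomicRanges::end(win) - 1L)  # short terminal windows
  win_chr <- as.character(GenomicRanges::seqnames(win))
  res <- list()
  for (cl in seq_len(n_classes)) {
    mg <- metagene_coordinate(win_chr, mid0, genes[class_of == cl], layout)
    dt <- data.table::data.table(w = seq_along(win), side = mg$side,
                                 offset = mg$offset)
    dt <- dt[!is.na(side) & offset >= -max_dist & offset < max_dist]
    dt <- merge(dt, cov, by = "w")
    if (nrow(dt) == 0L) next
    dt[, bin_lo := floor(offset / bin_width) * bin_width]
    agg <- dt[, list(mean_rate = sum(num) / sum(den),
                     covered_bp = sum(den)),
              by = c("side", "bin_lo")]
    agg[, expression_class := cl]
    res[[cl]] <- agg
  }
  if (!length(res)) {
    return(data.frame(expression_class = integer(), side = character(),
                      bin_lo = numeric(), bin_hi = numeric(),
                      mean_rate = numeric(), covered_bp = numeric()))
  }
  out <- data.table::rbindlist(res)
  out[, bin_hi := bin_lo + bin_width]
  out <- as.data.frame(out[order(expression_class, side, bin_lo),
                           c("expression_class", "side", "bin_lo", "bin_hi",
                             "mean_rate", "covered_bp"), with = FALSE])
  rownames(out) <- NULL
  out
}
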