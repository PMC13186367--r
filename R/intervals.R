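#' Merge an interval collection
#'
#' Sorts and merges overlapping or bookended intervals so that the result is
#' non-overlapping and non-adjacent while covering exactly the same bases.
#' Strand is ignored: merging operates on genomic position only.
#'
#' @param gr A `GRanges`.
#' @param layout Genome layout used for validation.
#' @return A sorted, reduced `GRanges`.
#' @export
merge_intervals <- function(gr, layout) {
  gr <- validate_intervals(gr, layout)
  GenomicRanges::reduce(GenomicRanges::sort(gr), ignore.strand = TRUE)
}

#' Complement of an interval collection within a genome
#'
#' Returns the bases of the genome not covered by `gr`. The union of input
#' and output covers every chromosome of the layout completely.
#'
#' @inheritParams merge_intervals
#' @return A `GRanges` of the uncovered bases.
#' @export
complement_intervals <- function(gr, layout) {
  gr <- validate_intervals(gr, layout)
  GenomicRanges::setdiff(genome_ranges(layout), gr, ignore.strand = TRUE)
}

#' Symmetric window around interval centers
#'
#' For each interval the center is `floor((start0 + end0) / 2)` in 0-based
#' coordinates; the window is `[center - halfwidth, center + halfwidth)`
#' clipped to the chromosome. With `halfwidth = 0` the window degenerates to
#' the single center base so that overlap remains well defined.
#'
#' @param gr `GRanges` of intervals.
#' @param halfwidth Window half-width in bp, `>= 0`.
#' @param layout Genome layout (used for clipping).
#' @return `GRanges` of windows, parallel to the input.
#' @export
window_around_center <- function(gr, halfwidth, layout) {
  stopifnot(halfwidth >= 0)
  gr <- validate_intervals(gr, layout)
  lens <- layout_lengths(layout)
  # 0-based center; GRanges start is 1-based so start0 = start - 1, end0 = end
  center0 <- floor((GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) / 2)
  if (halfwidth == 0) {
    s1 <- center0 + 1L
    e1 <- center0 + 1L
  } else {
    s1 <- center0 - halfwidth + 1L
    e1 <- center0 + halfwidth
  }
  chr <- as.character(GenomicRanges::seqnames(gr))
  s1 <- pmax(s1, 1L)
  e1 <- pmin(e1, lens[chr])
  out <- GenomicRanges::GRanges(chr, IRanges::IRanges(s1, e1))
  out <- set_layout(out, layout)
  out
}

#' Count queries that overlap at least one target
#'
#' Overlap means sharing at least one base on the same chromosome; strand is
#' ignored. Returns both the total count and the per-query indicator so that
#' downstream percentages can be formed.
#'
#' @param queries,targets `GRanges` collections on the same layout.
#' @param layout Genome layout.
#' @return List with `count` (scalar) and `hits` (logical vector parallel to
#'   `queries`).
#' @export
count_overlapping <- function(queries, targets, layout) {
  queries <- validate_intervals(queries, layout)
  targets <- validate_intervals(targets, layout)
  hits <- GenomicRanges::countOverlaps(queries, targets, ignore.strand = TRUE) > 0L
  list(count = sum(hits), hits = hits)
}
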