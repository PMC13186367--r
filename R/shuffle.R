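#' Constrained shuffle of peaks within the callable genome
#'
#' Draws a random relocation of every peak, preserving the number of peaks
#' and the exact multiset of peak lengths, with each shuffled peak required
#' to lie entirely inside one segment of the callable mask. The placement is
#' uniform over all legal placements genome-wide: a mask segment of length
#' `L` offers `L - w + 1` start positions to a peak of length `w`, a segment
#' is chosen with probability proportional to that number, and the start is
#' then uniform among the valid offsets. Shuffled peaks are not prevented
#' from overlapping each other.
#'
#' @param peaks `GRanges` peak set.
#' @param mask Callable mask from [build_callable_mask()].
#' @param seed Integer seed; the same seed reproduces the same shuffle. The
#'   caller's RNG state is left untouched.
#' @param layout Genome layout.
#' @return A `GRanges` with the same length and width multiset as `peaks`,
#'   unstranded, carrying the input's label.
#' @export
shuffle_peaks <- function(peaks, mask, seed, layout) {
  peaks <- validate_intervals(peaks, layout)
  mask <- validate_intervals(mask, layout)
  if (length(peaks) == 0L) return(peaks)
  w <- GenomicRanges::width(peaks)
  seg_len <- GenomicRanges::width(mask)
  too_long <- which(w > max(seg_len))
  if (length(too_long)) {
    i <- too_long[1L]
    stop(sprintf(
      "peak %d (%s:%d-%d, %d bp) is longer than every callable segment (max %d bp)",
      i, as.character(GenomicRanges::seqnames(peaks))[i],
      GenomicRanges::start(peaks)[i] - 1L, GenomicRanges::end(peaks)[i],
      w[i], max(seg_len)))
  }
  lidx <- linear_index(layout)
  sampler <- mask_sampler(mask, lidx)
  lin <- withr::with_seed(seed, draw_placements(w, sampler))
  pos <- delinearize(lin, lidx)
  out <- GenomicRanges::GRanges(pos$chrom,
                                IRanges::IRanges(as.integer(pos$pos0) + 1L,
                                                 width = w))
  out <- set_layout(out, layout)
  S4Vectors::metadata(out)$label <- peak_label(peaks)
  out
}
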