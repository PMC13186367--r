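#' Build the callable-genome mask
#'
#' The callable genome is where ChIP-seq peaks can in principle be called,
#' hence the only space in which null (shuffled) peaks may be placed. It is
#' the genome minus the union of (i) the ENCODE-style blacklist and (ii)
#' zero-coverage runs longer than `min_zero_run` bp — regions with no reads,
#' where a hotspot would be undetectable even if present.
#'
#' @param layout Genome layout.
#' @param blacklist `GRanges` of blacklisted regions (may be empty).
#' @param zero_coverage `GRanges` of zero-coverage runs (may be empty).
#' @param min_zero_run Zero-coverage runs of length `> min_zero_run` bp are
#'   excluded from the mask; shorter runs are kept callable. Default 1000.
#' @return A sorted, merged `GRanges` mask.
#' @export
build_callable_mask <- function(layout, blacklist = NULL, zero_coverage = NULL,
                                min_zero_run = 1000) {
  stopifnot(min_zero_run >= 0)
  excl <- GenomicRanges::GRanges()
  if (!is.null(blacklist) && length(blacklist)) {
    excl <- c(excl, GenomicRanges::granges(validate_intervals(blacklist, layout)))
  }
  if (!is.null(zero_coverage) && length(zero_coverage)) {
    zc <- validate_intervals(zero_coverage, layout)
    long <- zc[GenomicRanges::width(zc) > min_zero_run]
    if (length(long)) excl <- c(excl, GenomicRanges::granges(long))
  }
  mask <- if (length(excl)) {
    GenomicRanges::setdiff(genome_ranges(layout), excl, ignore.strand = TRUE)
  } else {
    genome_ranges(layout)
  }
  if (length(mask) == 0L) {
    stop("callable mask is empty: blacklist and zero-coverage runs cover the genome")
  }
  mask <- set_layout(mask, layout)
  GenomicRanges::sort(mask)
}
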