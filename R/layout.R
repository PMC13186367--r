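#' Declare a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths against
#' which every interval in a run is validated. It is represented as a
#' [GenomeInfoDb::Seqinfo] object so that it can be attached directly to the
#' `GRanges` containers used throughout the package.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp. Names are
#'   chromosome names; they must be unique and non-empty, lengths must be
#'   positive integers.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(lengths) {
  if (length(lengths) == 0L) stop("genome layout needs at least one chromosome")
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("all chromosome names must be non-empty")
  }
  if (anyDuplicated(nm)) {
    stop("duplicated chromosome name: ", nm[duplicated(nm)][1L])
  }
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("all chromosome lengths must be positive")
  }
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = as.integer(lengths))
}

#' @noRd
layout_lengths <- function(layout) {
  stats::setNames(as.numeric(GenomeInfoDb::seqlengths(layout)),
                  GenomeInfoDb::seqnames(layout))
}

#' Build a GRanges from BED-style (0-based half-open) coordinates
#'
#' External interval formats in this package follow the BED convention
#' (0-based start, exclusive end). Internally intervals are held as
#' `GRanges`, which are 1-based and closed; this constructor performs the
#' conversion and validates against a layout.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open span per interval.
#' @param layout A layout from [genome_layout()].
#' @param strand Optional strand vector ("+", "-", "*"); default unstranded.
#' @return A `GRanges` with the layout as its `seqinfo`.
#' @export
bed_ranges <- function(chrom, start, end, layout, strand = "*") {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = strand
  )
  validate_intervals(gr, layout)
}

#' Validate intervals against a genome layout
#'
#' Checks that every interval is non-empty and lies within the declared
#' chromosome bounds. On success the layout is attached as `seqinfo` and the
#' (possibly re-levelled) object returned; on failure the first offending
#' record is named in the error.
#'
#' @param gr A `GRanges`.
#' @param layout A layout from [genome_layout()].
#' @return The validated `GRanges`.
#' @export
validate_intervals <- function(gr, layout) {
  lens <- layout_lengths(layout)
  chr <- as.character(GenomicRanges::seqnames(gr))
  bad_chr <- which(!(chr %in% names(lens)))
  if (length(bad_chr)) {
    stop("interval ", bad_chr[1L], " on unknown chromosome '",
         chr[bad_chr[1L]], "'")
  }
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  bad <- which(s < 1L | e < s | e > lens[chr])
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf("invalid interval %d: %s:%d-%d outside layout (length %d)",
                 i, chr[i], s[i] - 1L, e[i], as.integer(lens[chr[i]])))
  }
  set_layout(gr, layout)
}

# attach a layout as seqinfo, tolerating any seqlevel order in the input
set_layout <- function(gr, layout) {
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- layout)
  gr
}

#' Whole-genome GRanges for a layout
#' @noRd
genome_ranges <- function(layout) {
  lens <- layout_lengths(layout)
  gr <- GenomicRanges::GRanges(names(lens), IRanges::IRanges(1L, as.integer(lens)))
  set_layout(gr, layout)
}

#' Construct a labelled peak set
#'
#' A peak set is a `GRanges` of peaks (hotspots, crossover or non-crossover
#' events, ChIP-seq peaks ...) carrying a free-text label, typically the
#' allele or assay name.
#'
#' @param intervals `GRanges` of peaks, validated against `layout`.
#' @param label Non-empty label string.
#' @param layout Genome layout.
#' @return A `GRanges` with `metadata(x)$label` set.
#' @export
peak_set <- function(intervals, label, layout) {
  if (!nzchar(label)) stop("peak set label must be non-empty")
  gr <- validate_intervals(intervals, layout)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' @noRd
peak_label <- function(peaks) {
  lab <- S4Vectors::metadata(peaks)$label
  if (is.null(lab)) "peaks" else lab
}
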