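# Linear-genome machinery.
#
# The permutation null needs tens of thousands of shuffle-and-count rounds,
# so the hot path works on a single linearised coordinate axis (chromosomes
# laid end to end, 0-based) with plain numeric vectors: placement is a
# vectorised binary search over cumulative placement weights and overlap
# counting is findInterval() against merged zone boundaries. The GRanges
# API functions are thin converters around these routines, so the public
# and internal paths share one implementation of the placement law and of
# the overlap definition.

linear_index <- function(layout) {
  lens <- layout_lengths(layout)
  list(chrom = names(lens), len = unname(lens),
       offset = stats::setNames(c(0, cumsum(lens))[seq_along(lens)], names(lens)),
       total = sum(lens))
}

# sampler over all legal placements of an interval in the mask: segments
# sorted by decreasing length so that the number of legal start offsets of
# a width-w interval is a prefix property
mask_sampler <- function(mask, lidx) {
  seg_chr <- as.character(GenomicRanges::seqnames(mask))
  seg_len <- GenomicRanges::width(mask)
  seg_lin <- lidx$offset[seg_chr] + GenomicRanges::start(mask) - 1  # 0-based
  ord <- order(seg_len, decreasing = TRUE)
  list(L = as.numeric(seg_len[ord]), P = cumsum(as.numeric(seg_len[ord])),
       lin = as.numeric(seg_lin[ord]), n_seg = length(ord))
}

# draw one uniform legal placement per width; RNG must be active.
# Returns 0-based linear start positions.
draw_placements <- function(widths, sampler) {
  n <- length(widths)
  if (n == 0L) return(numeric())
  L <- sampler$L
  P <- sampler$P
  # k = number of segments long enough for each width (L is sorted desc)
  k <- findInterval(-widths, -L)
  if (any(k == 0L)) {
    i <- which(k == 0L)[1L]
    stop("interval of ", widths[i], " bp is longer than every callable segment (max ",
         L[1L], " bp)")
  }
  total <- P[k] - k * (widths - 1)
  u <- pmin(floor(stats::runif(n) * total), total - 1)  # in [0, total - 1]
  # smallest m with C(m) > u, where C(m) = P[m] - m*(w-1) is the cumulative
  # number of placements over the m longest segments
  lo <- rep(0L, n)
  hi <- k
  repeat {
    act <- hi - lo > 1L
    if (!any(act)) break
    mid <- (lo + hi) %/% 2L
    cm <- P[pmax(mid, 1L)] - mid * (widths - 1)
    le <- act & cm <= u
    lo[le] <- mid[le]
    gt <- act & !le
    hi[gt] <- mid[gt]
  }
  c_lo <- ifelse(lo == 0L, 0, P[pmax(lo, 1L)] - lo * (widths - 1))
  sampler$lin[hi] + (u - c_lo)
}

# split 0-based linear positions back into chromosome coordinates
delinearize <- function(lin, lidx) {
  brk <- c(unname(lidx$offset), lidx$total)
  i <- findInterval(lin, brk)
  list(chrom = lidx$chrom[i], pos0 = lin - brk[i])
}

# merged, sorted, closed [lo, hi] linear zones within which a peak center
# triggers an overlap with a family element (see family_overlap_counts)
build_zone <- function(lo, hi) {
  keep <- hi >= lo
  lo <- lo[keep]
  hi <- hi[keep]
  if (!length(lo)) return(list(lo = numeric(), hi = numeric()))
  o <- order(lo)
  lo <- lo[o]
  hi <- hi[o]
  hmax <- cummax(hi)
  n <- length(lo)
  new_grp <- c(TRUE, lo[-1L] > hmax[-n] + 1)
  g_start <- which(new_grp)
  g_end <- c(g_start[-1L] - 1L, n)
  list(lo = lo[g_start], hi = hmax[g_end])
}

count_in_zone <- function(pos, zone) {
  if (!length(zone$lo)) return(0L)
  i <- findInterval(pos, zone$lo)
  sum(i >= 1L & pos <= zone$hi[pmax(i, 1L)])
}

# Per-family center-trigger zones in linear coordinates, clipped to
# chromosome bounds: the set of center positions at which a peak counts as
# overlapping an element [s0, e0) of the family.
#
# window mode, halfwidth hw > 0: the half-open window [c - hw, c + hw)
#   shares a base with the element iff c in [s0 - hw + 1, e0 + hw - 1]
#   (closed, 0-based); hw = 0 degenerates to the 1-bp window, c in
#   [s0, e0 - 1].
# center_distance mode: distance(c, element) < max_dist iff c in
#   [s0 - max_dist + 1, e0 + max_dist - 2].
family_zones <- function(repeats, families, lidx,
                         mode = c("window", "center_distance"),
                         halfwidth = 100, max_dist = 200) {
  mode <- match.arg(mode)
  chr <- as.character(GenomicRanges::seqnames(repeats))
  s0 <- GenomicRanges::start(repeats) - 1
  e0 <- as.numeric(GenomicRanges::end(repeats))
  off <- lidx$offset[chr]
  chrom_len <- stats::setNames(lidx$len, lidx$chrom)[chr]
  if (mode == "window") {
    ext_l <- if (halfwidth > 0) halfwidth - 1 else 0
    ext_r <- if (halfwidth > 0) halfwidth else 0
  } else {
    ext_l <- ext_r <- max_dist - 1
  }
  lo0 <- s0 - ext_l
  hi0 <- (e0 - 1) + ext_r
  lo <- off + pmax(lo0, 0)
  hi <- off + pmin(hi0, chrom_len - 1)
  fam <- repeats$family
  out <- lapply(families, function(f) {
    sel <- fam == f
    build_zone(lo[sel], hi[sel])
  })
  names(out) <- families
  out
}

# 0-based linear center positions of peaks given linear starts and widths
linear_centers <- function(lin_start, widths) {
  lin_start + floor(widths / 2)
}
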