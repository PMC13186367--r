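#' Per-family overlap of hotspot centers with repeat annotations
#'
#' For each repeat family, counts the peaks whose center `+/- halfwidth`
#' window intersects at least one element of that family. A peak can count
#' toward several families. The alternative `center_distance` mode instead
#' counts peaks whose center lies at less than `max_dist` bp from an
#' element of the family.
#'
#' @param peaks `GRanges` peak set (non-empty).
#' @param repeats `GRanges` with a `family` column.
#' @param layout Genome layout.
#' @param halfwidth Window half-width in bp (default 100).
#' @param families Families to report; defaults to those present in
#'   `repeats`. Families with no element report a zero count.
#' @param mode `"window"` (center +/- halfwidth intersects an element,
#'   default) or `"center_distance"` (center at < `max_dist` bp from an
#'   element).
#' @param max_dist Distance cutoff for `center_distance` mode (default 200).
#' @return data.frame `family`, `count`, `pct` (percentage of all peaks).
#' @export
family_overlap_counts <- function(peaks, repeats, layout, halfwidth = 100,
                                  families = NULL,
                                  mode = c("window", "center_distance"),
                                  max_dist = 200) {
  mode <- match.arg(mode)
  if (length(peaks) == 0L) stop("peak set is empty")
  peaks <- validate_intervals(peaks, layout)
  repeats <- validate_intervals(repeats, layout)
  if (is.null(repeats$family)) stop("repeat annotation lacks a family column")
  if (is.null(families)) families <- sort(unique(repeats$family))
  lidx <- linear_index(layout)
  zones <- family_zones(repeats, families, lidx, mode = mode,
                        halfwidth = halfwidth, max_dist = max_dist)
  centers <- peak_linear_centers(peaks, lidx)
  counts <- vapply(families, function(f) count_in_zone(centers, zones[[f]]), 0L)
  data.frame(family = families,
             count = as.integer(counts),
             pct = 100 * counts / length(peaks),
             stringsAsFactors = FALSE, row.names = NULL)
}

# 0-based linear center position of each peak (center = start0 + floor(w/2))
peak_linear_centers <- function(peaks, lidx) {
  chr <- as.character(GenomicRanges::seqnames(peaks))
  s0 <- GenomicRanges::start(peaks) - 1
  lidx$offset[chr] + s0 + floor(GenomicRanges::width(peaks) / 2)
}

#' Repeat-family enrichment of hotspots against a constrained-shuffle null
#'
#' Compares the observed per-family overlap of hotspot centers with the
#' overlap of shuffled hotspot sets placed uniformly in the callable genome
#' (see [shuffle_peaks()]). The chance expectation is the mean overlap over
#' the permutations; the enrichment ratio is observed / expected. The
#' significance rule is the permutation range rule: a family is `NS` when
#' the observed count lies within `[min, max]` of the null counts,
#' `enriched` when strictly above the maximum, `depleted` when strictly
#' below the minimum. A one-sided empirical p-value
#' `(1 + #{null >= observed}) / (n + 1)` is reported as a diagnostic.
#'
#' @param peaks `GRanges` peak set; every peak must lie within the mask
#'   (otherwise the null could never produce it).
#' @param repeats `GRanges` repeat annotation with `family` column.
#' @param mask Callable mask from [build_callable_mask()].
#' @param layout Genome layout.
#' @param n_permutations Number of shuffled replicates (default 40).
#' @param halfwidth Center-window half-width in bp (default 100).
#' @param seed Integer seed; permutation `i` uses `seed + i`.
#' @param families,mode,max_dist Passed to [family_overlap_counts()].
#' @return A list of class `enrichment_result`: `summary` (data.frame with
#'   `family`, `observed_count`, `observed_pct`, `null_mean`, `null_min`,
#'   `null_max`, `null_mean_pct`, `ratio`, `p_emp`, `call`) and
#'   `null_counts` (matrix family x permutation, for audit).
#' @export
enrichment_test <- function(peaks, repeats, mask, layout, n_permutations = 40,
                            halfwidth = 100, seed = 1, families = NULL,
                            mode = c("window", "center_distance"),
                            max_dist = 200) {
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  peaks <- validate_intervals(peaks, layout)
  mask <- validate_intervals(mask, layout)
  outside <- GenomicRanges::countOverlaps(peaks, mask, type = "within") == 0L
  if (any(outside)) {
    i <- which(outside)[1L]
    stop(sprintf("peak %d (%s:%d-%d) is not contained in the callable mask",
                 i, as.character(GenomicRanges::seqnames(peaks))[i],
                 GenomicRanges::start(peaks)[i] - 1L,
                 GenomicRanges::end(peaks)[i]))
  }
  repeats <- validate_intervals(repeats, layout)
  if (is.null(families)) families <- sort(unique(repeats$family))
  obs <- family_overlap_counts(peaks, repeats, layout, halfwidth = halfwidth,
                               families = families, mode = mode,
                               max_dist = max_dist)
  # permutation i re-places the peaks in the mask with seed + i; shares the
  # placement sampler and zone index with shuffle_peaks()/
  # family_overlap_counts() so the loop avoids per-replicate container
  # construction while computing exactly their composition
  lidx <- linear_index(layout)
  sampler <- mask_sampler(mask, lidx)
  zones <- family_zones(repeats, families, lidx, mode = mode,
                        halfwidth = halfwidth, max_dist = max_dist)
  w <- GenomicRanges::width(peaks)
  null_counts <- matrix(0L, nrow = length(families), ncol = n_permutations,
                        dimnames = list(families, NULL))
  for (i in seq_len(n_permutations)) {
    lin <- withr::with_seed(seed + i, draw_placements(w, sampler))
    centers <- linear_centers(lin, w)
    null_counts[, i] <- vapply(families, function(f) {
      count_in_zone(centers, zones[[f]])
    }, 0L)
  }
  null_mean <- rowMeans(null_counts)
  null_min <- apply(null_counts, 1L, min)
  null_max <- apply(null_counts, 1L, max)
  k <- obs$count
  ratio <- ifelse(null_mean > 0, k / null_mean,
                  ifelse(k > 0, Inf, NA_real_))
  call <- ifelse(k > null_max, "enriched",
                 ifelse(k < null_min, "depleted", "NS"))
  p_emp <- (1 + rowSums(null_counts >= k)) / (n_permutations + 1)
  N <- length(peaks)
  summary <- data.frame(
    family = families,
    observed_count = k,
    observed_pct = obs$pct,
    null_mean = null_mean,
    null_min = as.integer(null_min),
    null_max = as.integer(null_max),
    null_mean_pct = 100 * null_mean / N,
    ratio = ratio,
    p_emp = p_emp,
    call = call,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(summary = summary, null_counts = null_counts,
                 n_peaks = N, n_permutations = n_permutations,
                 halfwidth = halfwidth, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Repeat-family enrichment: %d peaks, %d permutations, halfwidth %d bp\n",
              x$n_peaks, x$n_permutations, x$halfwidth))
  print(x$summary, digits = 3)
  invisible(x)
}
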