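#' Assign genes to expression categories and build their territories
#'
#' Genes are ranked by expression (ties broken by gene id) and split into
#' `n_quantiles` nearly equal groups, category 1 holding the least expressed
#' genes. Each category's territory is the merged union of its member gene
#' spans minus the blacklist; the additional `intergenic` category is the
#' genome minus all gene spans minus the blacklist. Genes with no expression
#' value are dropped (default) or treated as zero.
#'
#' @param genes `GRanges` with a `gene_id` column.
#' @param expression Named numeric vector, gene id -> expression.
#' @param n_quantiles Number of expression quantiles (default 5).
#' @param layout Genome layout.
#' @param blacklist Optional `GRanges` of blacklisted regions.
#' @param missing One of `"drop"` (default) or `"zero"`: how to treat genes
#'   absent from the expression table.
#' @return A list of class `expression_categories` with elements
#'   `assignment` (data.frame gene_id/category), `territories` (named list of
#'   `GRanges`, names `"1"` ... `"<n>"` and `"intergenic"`),
#'   `territory_length` (named numeric, bp) and `n_quantiles`.
#' @export
assign_expression_categories <- function(genes, expression, n_quantiles = 5,
                                         layout, blacklist = NULL,
                                         missing = c("drop", "zero")) {
  missing <- match.arg(missing)
  genes <- validate_intervals(genes, layout)
  ids <- genes$gene_id
  if (is.null(ids)) stop("genes must carry a gene_id column")
  expr <- expression[ids]
  if (anyNA(expr)) {
    n_missing <- sum(is.na(expr))
    if (missing == "drop") {
      message(n_missing, " gene(s) without expression value dropped")
      keep <- !is.na(expr)
      genes <- genes[keep]
      ids <- ids[keep]
      expr <- expr[keep]
    } else {
      expr[is.na(expr)] <- 0
    }
  }
  n_genes <- length(genes)
  if (n_genes < n_quantiles) {
    stop("fewer genes (", n_genes, ") than quantiles (", n_quantiles, ")")
  }
  # rank ascending by expression, ties by gene id, then balanced split
  o <- order(expr, ids)
  category <- integer(n_genes)
  category[o] <- floor((seq_len(n_genes) - 1) * n_quantiles / n_genes) + 1L
  bl <- if (is.null(blacklist) || length(blacklist) == 0L) {
    GenomicRanges::GRanges()
  } else {
    merge_intervals(blacklist, layout)
  }
  subtract_bl <- function(gr) {
    if (length(bl)) GenomicRanges::setdiff(gr, bl, ignore.strand = TRUE) else gr
  }
  territories <- lapply(seq_len(n_quantiles), function(k) {
    subtract_bl(merge_intervals(genes[category == k], layout))
  })
  names(territories) <- as.character(seq_len(n_quantiles))
  all_genes <- merge_intervals(genes, layout)
  territories$intergenic <- subtract_bl(complement_intervals(all_genes, layout))
  structure(list(
    assignment = data.frame(gene_id = ids, category = category,
                            expression = unname(expr),
                            stringsAsFactors = FALSE),
    territories = territories,
    territory_length = vapply(territories, function(g) sum(as.numeric(GenomicRanges::width(g))), 0),
    n_quantiles = n_quantiles,
    blacklist = bl,
    layout = layout
  ), class = "expression_categories")
}

#' Relative peak density per expression category
#'
#' Counts peaks per category territory and normalises to a relative density
#' comparable across categories of different total length: for category *c*
#' with `k_c` peaks over `L_c` bp and `N` retained peaks genome-wide,
#' `density = k_c / L_c` and `relative_density = (k_c / L_c) / N`. The
#' sampling error on the peak fraction `p = k_c / N` is binomial,
#' `se_relative = sqrt(p (1 - p) / N) / L_c`.
#'
#' Peaks falling in the blacklist (where peaks cannot be called) are
#' excluded from `N` and from every count. In `midpoint` mode each peak is
#' assigned to the single category whose territory contains its center, so
#' counts are conserved (`sum(k_c) = N`); where gene territories of several
#' categories overlap a center, the highest category index wins. In
#' `any_overlap` mode a peak counts in every category its span intersects.
#'
#' @param peaks `GRanges` peak set.
#' @param categories Result of [assign_expression_categories()].
#' @param mode `"midpoint"` (default) or `"any_overlap"`.
#' @return A data.frame with one row per category: `category`, `peak_count`,
#'   `territory_bp`, `total_peaks`, `density`, `relative_density`,
#'   `se_relative`. A category with zero territory length gets `NA`
#'   densities (undefined, not zero).
#' @export
peak_density_by_category <- function(peaks, categories,
                                     mode = c("midpoint", "any_overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(categories, "expression_categories"))
  layout <- categories$layout
  peaks <- validate_intervals(peaks, layout)
  bl <- categories$blacklist
  terr <- categories$territories
  cat_names <- names(terr)
  if (mode == "midpoint") {
    centers <- window_around_center(peaks, 0, layout)
    if (length(bl)) {
      in_bl <- GenomicRanges::countOverlaps(centers, bl) > 0L
      centers <- centers[!in_bl]
    }
    N <- length(centers)
    if (N == 0L) stop("no peaks outside the blacklist; nothing to count")
    # assign each center to one category; later (higher) categories take
    # precedence where territories overlap, intergenic only if in no gene
    assigned <- rep(NA_character_, N)
    for (nm in cat_names) {
      hit <- GenomicRanges::countOverlaps(centers, terr[[nm]]) > 0L
      assigned[hit & nm != "intergenic"] <- nm
      assigned[hit & nm == "intergenic" & is.na(assigned)] <- nm
    }
    k <- vapply(cat_names, function(nm) sum(assigned == nm, na.rm = TRUE), 0)
  } else {
    if (length(bl)) {
      in_bl <- GenomicRanges::countOverlaps(peaks, bl) > 0L
      peaks <- peaks[!in_bl]
    }
    N <- length(peaks)
    if (N == 0L) stop("no peaks outside the blacklist; nothing to count")
    k <- vapply(cat_names, function(nm) {
      sum(GenomicRanges::countOverlaps(peaks, terr[[nm]]) > 0L)
    }, 0)
  }
  L <- categories$territory_length[cat_names]
  p_hat <- k / N
  density <- ifelse(L > 0, k / L, NA_real_)
  res <- data.frame(
    category = cat_names,
    peak_count = as.integer(k),
    territory_bp = as.numeric(L),
    total_peaks = as.integer(N),
    density = density,
    relative_density = ifelse(L > 0, density / N, NA_real_),
    se_relative = ifelse(L > 0, sqrt(p_hat * (1 - p_hat) / N) / L, NA_real_),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  res
}
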