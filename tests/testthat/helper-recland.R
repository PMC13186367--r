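suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

tiny_layout <- function(lens = c(chr1 = 10000, chr2 = 6000)) {
  genome_layout(lens)
}

# random BED-style intervals on a layout (caller controls the RNG)
random_bed <- function(n, layout, max_width = 200) {
  lens <- stats::setNames(as.numeric(GenomeInfoDb::seqlengths(layout)),
                          GenomeInfoDb::seqnames(layout))
  chr <- sample(names(lens), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  w <- pmin(w, lens[chr])
  s <- floor(runif(n) * (lens[chr] - w + 1))
  bed_ranges(chr, s, s + w, layout)
}

# per-base boolean-coverage oracle: covered positions (0-based) per chrom
coverage_positions <- function(gr, layout) {
  lens <- stats::setNames(as.numeric(GenomeInfoDb::seqlengths(layout)),
                          GenomeInfoDb::seqnames(layout))
  out <- lapply(names(lens), function(ch) {
    v <- logical(lens[[ch]])
    sel <- as.character(seqnames(gr)) == ch
    for (i in which(sel)) {
      v[seq(start(gr)[i], end(gr)[i])] <- TRUE
    }
    which(v)
  })
  names(out) <- names(lens)
  out
}

# O(n*m) brute-force overlap scan (>= 1 shared base, any chromosome)
brute_force_hits <- function(queries, targets) {
  qc <- as.character(seqnames(queries)); qs <- start(queries); qe <- end(queries)
  tc <- as.character(seqnames(targets)); ts <- start(targets); te <- end(targets)
  vapply(seq_along(queries), function(i) {
    any(qc[i] == tc & qs[i] <= te & qe[i] >= ts)
  }, logical(1))
}

# small, fast synthetic dataset used by several suites
small_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosomes = 2, chromosome_length = 2e6,
         n_genes = 150, n_hotspots = 400),
    list(...))
  do.call(synthetic_config, args)
}

# matching JSON config for CLI-level tests
write_small_cli_config <- function(dir, seed = 7) {
  path <- file.path(dir, "config.json")
  jsonlite::write_json(list(seed = seed, n_chromosomes = 2,
                            chromosome_length = 2e6, n_genes = 150,
                            n_hotspots = 400),
                       path, auto_unbox = TRUE)
  path
}
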