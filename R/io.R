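#' @import methods
#' @importFrom data.table data.table as.data.table setorderv :=
NULL

# open a connection, transparently handling .gz by suffix
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_lines_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

is_skippable <- function(lines) {
  grepl("^(#|track\\b|browser\\b)", lines) | !nzchar(trimws(lines))
}

#' Read a chromosome-sizes table as a genome layout
#'
#' Two-column tab-separated file (chromosome name, length in bp), the UCSC
#' `chrom.sizes` convention. Lines starting with `#` are skipped.
#'
#' @param path Path to the file (plain or gzip).
#' @return A layout as returned by [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  lines <- read_lines_auto(path)
  keep <- !is_skippable(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 2L)) {
    stop("line ", which(keep)[which(n < 2L)[1L]], ": expected 2 columns")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(len)) {
    stop("line ", which(keep)[which(is.na(len))[1L]], ": non-numeric length")
  }
  genome_layout(stats::setNames(len, nm))
}

#' Read an interval file (BED3, BED6 or narrowPeak) as a peak set
#'
#' Coordinates are BED-convention 0-based half-open and are converted to the
#' internal 1-based representation. `track`/`browser`/comment lines are
#' skipped. Coordinates outside the layout raise an error rather than being
#' clipped.
#'
#' @param path Path to the file (plain or gzip).
#' @param layout Genome layout.
#' @param dialect One of `"BED3"`, `"BED6"`, `"narrowPeak"`; sets the minimum
#'   column count and whether strand is read (column 6).
#' @param label Peak-set label; defaults to the file stem.
#' @return A labelled `GRanges` peak set.
#' @export
read_intervals <- function(path, layout, dialect = c("BED3", "BED6", "narrowPeak"),
                           label = NULL) {
  dialect <- match.arg(dialect)
  min_cols <- switch(dialect, BED3 = 3L, BED6 = 6L, narrowPeak = 10L)
  if (is.null(label)) {
    label <- sub("\\.gz$", "", basename(path))
    label <- sub("\\.[^.]*$", "", label)
  }
  lines <- read_lines_auto(path)
  keep <- which(!is_skippable(lines))
  if (!length(keep)) {
    return(peak_set(GenomicRanges::GRanges(), label, layout))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol_line <- lengths(fields)
  bad <- which(ncol_line < min_cols)
  if (length(bad)) {
    stop(sprintf("line %d: %s requires >= %d columns, found %d",
                 keep[bad[1L]], dialect, min_cols, ncol_line[bad[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("line ", keep[which(is.na(start) | is.na(end))[1L]],
         ": non-numeric coordinate")
  }
  strand <- if (min_cols >= 6L) {
    s <- vapply(fields, `[[`, "", 6L)
    ifelse(s %in% c("+", "-"), s, "*")
  } else "*"
  gr <- bed_ranges(chrom, start, end, layout, strand = strand)
  peak_set(gr, label, layout)
}

#' Write intervals as BED
#'
#' Emits BED3 (plus strand as BED6 when any interval is stranded) with
#' 0-based half-open coordinates, sorted by chromosome then start.
#'
#' @param gr `GRanges` to write.
#' @param path Output path.
#' @param name Optional name column (recycled); triggers BED6 output.
#' @export
write_bed <- function(gr, path, name = NULL) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (is.null(name) && all(strand == "*")) {
    out <- paste(chrom, start0, end0, sep = "\t")
  } else {
    nm <- if (is.null(name)) "." else rep_len(name, length(gr))
    out <- paste(chrom, start0, end0, nm, 0L,
                 ifelse(strand == "*", ".", strand), sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a UCSC RepeatMasker table as a repeat annotation
#'
#' Expects the Table Browser export with a header naming at least
#' `genoName`, `genoStart`, `genoEnd`, `strand`, `repName`, `repClass` and
#' `repFamily`. Records whose family (or class, per `key`) is in `families`
#' are retained; the rest are dropped and the counts reported as attributes.
#'
#' @param path Path to the table (plain or gzip, tab-separated, with header;
#'   a leading `#` on the header line is tolerated).
#' @param layout Genome layout.
#' @param families Character vector of family labels to retain.
#' @param key `"repFamily"` (default) or `"repClass"`: which column supplies
#'   the family label.
#' @return A `GRanges` with a `family` metadata column; attributes
#'   `n_retained` and `n_dropped` carry the filter report.
#' @export
read_repeatmasker <- function(path, layout, families, key = c("repFamily", "repClass")) {
  key <- match.arg(key)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  names(dt)[1L] <- sub("^#", "", names(dt)[1L])
  need <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
            "repClass", "repFamily")
  missing_col <- setdiff(need, names(dt))
  if (length(missing_col)) {
    stop("RepeatMasker table is missing column(s): ",
         paste(missing_col, collapse = ", "))
  }
  fam <- dt[[key]]
  keep <- fam %in% families
  n_drop <- sum(!keep)
  dt <- dt[keep]
  gr <- bed_ranges(dt$genoName, dt$genoStart, dt$genoEnd, layout,
                   strand = ifelse(dt$strand %in% c("+", "-"), dt$strand, "*"))
  S4Vectors::mcols(gr)$family <- dt[[key]]
  attr(gr, "n_retained") <- length(gr)
  attr(gr, "n_dropped") <- n_drop
  gr
}

#' Read gene models from a GTF file
#'
#' Uses `gene` records where present, otherwise reduces `transcript` (or
#' `exon`) records to one outermost span per `gene_id`. GTF 1-based
#' inclusive coordinates become the internal representation directly; the
#' TSS is the 5' end of the span and the TES the 3' end, by strand.
#'
#' @param path Path to the GTF (plain or gzip).
#' @param layout Genome layout.
#' @return A `GRanges` with metadata columns `gene_id`, `tss`, `tes`
#'   (0-based bp positions of the strand-oriented start and end sites).
#' @export
read_genes_gtf <- function(path, layout) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) stop("GTF contains no records: ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("GTF record without gene_id attribute")
  }
  type <- as.character(gr$type)
  use <- if (any(type == "gene")) gr[type == "gene"] else gr
  # outermost span per gene across its records
  spl <- S4Vectors::split(use, use$gene_id)
  spans <- unlist(range(spl, ignore.strand = FALSE))
  ids <- names(spans)
  names(spans) <- NULL
  if (any(as.character(GenomicRanges::strand(spans)) == "*")) {
    bad <- ids[as.character(GenomicRanges::strand(spans)) == "*"][1L]
    stop("gene ", bad, " has no strand; TSS/TES are undefined")
  }
  spans <- validate_intervals(spans, layout)
  S4Vectors::mcols(spans)$gene_id <- ids
  gene_tss_tes(spans)
}

# annotate strand-oriented tss/tes (0-based positions) on a gene GRanges
gene_tss_tes <- function(genes) {
  s0 <- GenomicRanges::start(genes) - 1L
  e0 <- GenomicRanges::end(genes)   # exclusive
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  S4Vectors::mcols(genes)$tss <- ifelse(plus, s0, e0 - 1L)
  S4Vectors::mcols(genes)$tes <- ifelse(plus, e0 - 1L, s0)
  genes
}

#' Write gene models as GTF
#'
#' One `gene` record per model, 1-based inclusive coordinates, `gene_id`
#' attribute only. Companion writer to [read_genes_gtf()].
#'
#' @param genes `GRanges` with `gene_id` metadata column.
#' @param path Output path.
#' @export
write_genes_gtf <- function(genes, path) {
  o <- order(as.character(GenomicRanges::seqnames(genes)),
             GenomicRanges::start(genes))
  genes <- genes[o]
  lines <- sprintf(
    "%s\trecland\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    as.character(GenomicRanges::seqnames(genes)),
    GenomicRanges::start(genes), GenomicRanges::end(genes),
    as.character(GenomicRanges::strand(genes)), genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a recombination map from a bedGraph file
#'
#' Four tab-separated columns: chromosome, 0-based start, exclusive end,
#' rate (cM/Mb). Overlapping records are rejected as ambiguous; negative
#' rates are a validation error.
#'
#' @param path Path (plain or gzip).
#' @param layout Genome layout.
#' @return A `GRanges` with a numeric `rate` metadata column.
#' @export
read_recmap_bedgraph <- function(path, layout) {
  lines <- read_lines_auto(path)
  keep <- which(!is_skippable(lines))
  if (!length(keep)) stop("recombination map is empty: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) {
    stop("line ", keep[bad[1L]], ": bedGraph requires 4 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  rate <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  if (anyNA(start) || anyNA(end) || anyNA(rate)) {
    stop("line ", keep[which(is.na(start) | is.na(end) | is.na(rate))[1L]],
         ": non-numeric field")
  }
  if (any(rate < 0)) {
    stop("line ", keep[which(rate < 0)[1L]], ": negative recombination rate")
  }
  gr <- bed_ranges(chrom, start, end, layout)
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(self)) {
    stop("overlapping recombination-map records (e.g. records ",
         S4Vectors::queryHits(self)[1L], " and ",
         S4Vectors::subjectHits(self)[1L], "): rate is ambiguous")
  }
  S4Vectors::mcols(gr)$rate <- rate
  GenomicRanges::sort(gr)
}

#' Write a recombination map as bedGraph
#' @param recmap `GRanges` with a `rate` column.
#' @param path Output path.
#' @export
write_recmap_bedgraph <- function(recmap, path) {
  recmap <- GenomicRanges::sort(recmap)
  writeLines(sprintf("%s\t%d\t%d\t%s",
                     as.character(GenomicRanges::seqnames(recmap)),
                     GenomicRanges::start(recmap) - 1L,
                     GenomicRanges::end(recmap),
                     format_num(recmap$rate)), path)
  invisible(path)
}

#' Read a gene-expression table
#'
#' Tab-separated with a header; the id and value columns are selected by
#' name. Duplicate gene ids and non-numeric or negative values are errors.
#'
#' @param path Path (plain or gzip).
#' @param id_col Name of the gene-id column (default `"gene_id"`).
#' @param value_col Name of the numeric value column; default: the second
#'   column of the file.
#' @return A named numeric vector, gene id -> expression value.
#' @export
read_expression_tsv <- function(path, id_col = "gene_id", value_col = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                          colClasses = list(character = 1))
  if (!(id_col %in% names(dt))) stop("missing id column '", id_col, "'")
  if (is.null(value_col)) value_col <- names(dt)[2L]
  if (!(value_col %in% names(dt))) stop("missing value column '", value_col, "'")
  ids <- as.character(dt[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id in expression table: ", ids[duplicated(ids)][1L])
  }
  vals <- dt[[value_col]]
  if (!is.numeric(vals)) {
    vals2 <- suppressWarnings(as.numeric(vals))
    if (anyNA(vals2)) {
      stop("non-numeric expression value for gene ", ids[which(is.na(vals2))[1L]])
    }
    vals <- vals2
  }
  if (any(vals < 0)) {
    stop("negative expression value for gene ", ids[which(vals < 0)[1L]])
  }
  stats::setNames(as.numeric(vals), ids)
}

# fixed 6-significant-digit formatting shared by all writers
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return(if (v > 0) "Inf" else "-Inf")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%d", as.integer(v)))
    sprintf("%.6g", v)
  }, "")
  out
}

#' Write a result table deterministically
#'
#' Tab-separated with header, rows sorted lexicographically over all
#' columns, numeric values formatted at 6 significant digits — so identical
#' inputs always produce byte-identical files.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_table <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) > 1L) {
    df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(unname(as.list(out)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a table written by [write_table()]
#' @param path Path to the TSV.
#' @return A data.frame with numeric columns restored.
#' @export
read_table_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  dt
}
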