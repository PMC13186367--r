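#' @importFrom utils packageVersion
NULL

recland_error <- function(msg) {
  structure(class = c("recland_error", "error", "condition"),
            list(message = msg, call = NULL))
}

usage_error <- function(msg) {
  structure(class = c("recland_usage_error", "error", "condition"),
            list(message = msg, call = NULL))
}

log_msg <- function(level, ..., min_level = getOption("recland.log_level", "INFO")) {
  lvl <- c(DEBUG = 1, INFO = 2, WARN = 3)
  if (lvl[[level]] >= lvl[[min_level]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

# manifest written next to every stage output: enough to re-run and to
# check that two runs saw identical inputs
write_manifest <- function(path, command, args, inputs, outputs, seed = NULL) {
  digest_of <- function(p) unname(tools::md5sum(p))
  inputs <- Filter(function(p) is.character(p) && file.exists(p), inputs)
  outputs <- Filter(function(p) is.character(p) && file.exists(p), outputs)
  manifest <- list(
    tool = "recland",
    version = as.character(utils::packageVersion("recland")),
    command = command,
    arguments = args,
    seed = seed,
    inputs = lapply(inputs, digest_of),
    outputs = lapply(outputs, digest_of),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the hotspot-density stage on files
#'
#' Reads the inputs, assigns expression quantiles, counts peaks per
#' category and writes the density table plus a run manifest.
#'
#' @param peaks_file,genes_file,expr_file,genome_file,blacklist_file Input
#'   paths (BED/narrowPeak, GTF, expression TSV, chrom sizes,
#'   optional BED).
#' @param out Output TSV path.
#' @param quantiles Number of expression quantiles (default 5).
#' @param mode Peak assignment mode, `"midpoint"` or `"any_overlap"`.
#' @param dialect Peak-file dialect for [read_intervals()].
#' @return The density data.frame, invisibly.
#' @export
stage_density <- function(peaks_file, genes_file, expr_file, genome_file,
                          blacklist_file = NULL, out, quantiles = 5,
                          mode = "midpoint", dialect = "BED3") {
  layout <- read_genome_layout(genome_file)
  peaks <- read_intervals(peaks_file, layout, dialect)
  genes <- read_genes_gtf(genes_file, layout)
  expr <- read_expression_tsv(expr_file)
  blacklist <- if (!is.null(blacklist_file)) {
    read_intervals(blacklist_file, layout, "BED3")
  } else NULL
  cats <- assign_expression_categories(genes, expr, quantiles, layout, blacklist)
  res <- peak_density_by_category(peaks, cats, mode)
  write_table(res, out)
  write_manifest(paste0(out, ".manifest.json"), "density",
                 list(quantiles = quantiles, mode = mode),
                 inputs = list(peaks = peaks_file, genes = genes_file,
                               expression = expr_file, genome = genome_file,
                               blacklist = blacklist_file),
                 outputs = list(table = out))
  log_msg("INFO", "density: ", nrow(res), " categories, ",
          res$total_peaks[1L], " peaks -> ", out)
  invisible(res)
}

#' Run the TSS/TES recombination-profile stage on files
#'
#' @param recmap_file,genes_file,expr_file,genome_file Input paths
#'   (bedGraph, GTF, expression TSV, chrom sizes).
#' @param out Output TSV path.
#' @param classes Number of expression classes (default 3).
#' @param window_width,bin_width,max_dist See [recombination_profile()].
#' @return The profile data.frame, invisibly.
#' @export
stage_profile <- function(recmap_file, genes_file, expr_file, genome_file,
                          out, classes = 3, window_width = 1000,
                          bin_width = 1000, max_dist = 50000) {
  layout <- read_genome_layout(genome_file)
  recmap <- read_recmap_bedgraph(recmap_file, layout)
  genes <- read_genes_gtf(genes_file, layout)
  expr <- read_expression_tsv(expr_file)
  res <- recombination_profile(recmap, genes, expr, layout, classes,
                               window_width, bin_width, max_dist)
  write_table(res, out)
  write_manifest(paste0(out, ".manifest.json"), "profile",
                 list(classes = classes, window_width = window_width,
                      bin_width = bin_width, max_dist = max_dist),
                 inputs = list(recmap = recmap_file, genes = genes_file,
                               expression = expr_file, genome = genome_file),
                 outputs = list(table = out))
  log_msg("INFO", "profile: ", nrow(res), " bins -> ", out)
  invisible(res)
}

#' Run the repeat-enrichment stage on files
#'
#' @param peaks_file,rmsk_file,genome_file Input paths.
#' @param blacklist_file,zerocov_file Optional mask inputs (BED).
#' @param out Output TSV path.
#' @param families Families to test; default: all in the RepeatMasker file.
#' @param min_zero_run,nperm,halfwidth,seed See [build_callable_mask()] and
#'   [enrichment_test()].
#' @param dialect Peak-file dialect.
#' @param rmsk_key `"repFamily"` or `"repClass"`.
#' @return The `enrichment_result`, invisibly.
#' @export
stage_enrich <- function(peaks_file, rmsk_file, genome_file,
                         blacklist_file = NULL, zerocov_file = NULL, out,
                         families = NULL, min_zero_run = 1000, nperm = 40,
                         halfwidth = 100, seed = 42, dialect = "BED3",
                         rmsk_key = "repFamily") {
  layout <- read_genome_layout(genome_file)
  peaks <- read_intervals(peaks_file, layout, dialect)
  if (is.null(families)) {
    all_fam <- data.table::fread(rmsk_file, sep = "\t", header = TRUE,
                                 select = rmsk_key)[[1L]]
    families <- sort(unique(all_fam))
  }
  repeats <- read_repeatmasker(rmsk_file, layout, families, rmsk_key)
  blacklist <- if (!is.null(blacklist_file)) {
    read_intervals(blacklist_file, layout, "BED3")
  } else NULL
  zerocov <- if (!is.null(zerocov_file)) {
    read_intervals(zerocov_file, layout, "BED3")
  } else NULL
  mask <- build_callable_mask(layout, blacklist, zerocov, min_zero_run)
  res <- enrichment_test(peaks, repeats, mask, layout, nperm, halfwidth,
                         seed, families = families)
  write_table(res$summary, out)
  perm <- data.frame(family = rownames(res$null_counts),
                     res$null_counts, check.names = FALSE)
  names(perm)[-1L] <- paste0("perm_", seq_len(ncol(res$null_counts)))
  write_table(perm, paste0(out, ".permutations.tsv"))
  write_manifest(paste0(out, ".manifest.json"), "enrich",
                 list(nperm = nperm, halfwidth = halfwidth,
                      min_zero_run = min_zero_run),
                 inputs = list(peaks = peaks_file, rmsk = rmsk_file,
                               genome = genome_file,
                               blacklist = blacklist_file,
                               zerocov = zerocov_file),
                 outputs = list(table = out), seed = seed)
  log_msg("INFO", "enrich: ", nrow(res$summary), " families, ",
          res$n_peaks, " peaks -> ", out)
  invisible(res)
}

#' Run the simulate stage on files
#'
#' @param outdir Output directory.
#' @param config_file Optional JSON file of [synthetic_config()] arguments.
#' @param seed Seed overriding the config's.
#' @return The written file paths, invisibly.
#' @export
stage_simulate <- function(outdir, config_file = NULL, seed = NULL) {
  args <- if (!is.null(config_file)) {
    jsonlite::read_json(config_file, simplifyVector = TRUE)
  } else list()
  if (!is.null(args$repeat_families)) {
    args$repeat_families <- lapply(args$repeat_families, as.list)
  }
  if (!is.null(seed)) args$seed <- seed
  config <- do.call(synthetic_config, args)
  paths <- simulate_dataset(config, outdir)
  write_manifest(file.path(outdir, "manifest.json"), "simulate",
                 list(config_file = config_file),
                 inputs = list(config = config_file),
                 outputs = as.list(paths), seed = config$seed)
  log_msg("INFO", "simulate: dataset written to ", outdir)
  invisible(paths)
}

opt <- function(flags, ...) optparse::make_option(flags, ...)

cli_specs <- function() {
  list(
    simulate = list(
      opts = list(
        opt("--outdir", type = "character", help = "output directory [required]"),
        opt("--config", type = "character", default = NULL,
            help = "JSON config for the generator"),
        opt("--seed", type = "integer", default = NULL, help = "seed override")),
      required = "outdir"),
    density = list(
      opts = list(
        opt("--peaks", type = "character", help = "peak BED/narrowPeak [required]"),
        opt("--genes", type = "character", help = "gene GTF [required]"),
        opt("--expr", type = "character", help = "expression TSV [required]"),
        opt("--genome", type = "character", help = "chrom sizes TSV [required]"),
        opt("--blacklist", type = "character", default = NULL),
        opt("--quantiles", type = "integer", default = 5L),
        opt("--mode", type = "character", default = "midpoint"),
        opt("--dialect", type = "character", default = "BED3"),
        opt("--out", type = "character", help = "output TSV [required]")),
      required = c("peaks", "genes", "expr", "genome", "out")),
    profile = list(
      opts = list(
        opt("--recmap", type = "character", help = "bedGraph map [required]"),
        opt("--genes", type = "character", help = "gene GTF [required]"),
        opt("--expr", type = "character", help = "expression TSV [required]"),
        opt("--genome", type = "character", help = "chrom sizes TSV [required]"),
        opt("--classes", type = "integer", default = 3L),
        opt("--window-width", type = "integer", default = 1000L, dest = "window_width"),
        opt("--bin-width", type = "integer", default = 1000L, dest = "bin_width"),
        opt("--max-dist", type = "integer", default = 50000L, dest = "max_dist"),
        opt("--out", type = "character", help = "output TSV [required]")),
      required = c("recmap", "genes", "expr", "genome", "out")),
    enrich = list(
      opts = list(
        opt("--peaks", type = "character", help = "peak BED/narrowPeak [required]"),
        opt("--rmsk", type = "character", help = "RepeatMasker table [required]"),
        opt("--genome", type = "character", help = "chrom sizes TSV [required]"),
        opt("--blacklist", type = "character", default = NULL),
        opt("--zerocov", type = "character", default = NULL),
        opt("--min-zero-run", type = "integer", default = 1000L, dest = "min_zero_run"),
        opt("--nperm", type = "integer", default = 40L),
        opt("--halfwidth", type = "integer", default = 100L),
        opt("--seed", type = "integer", default = 42L),
        opt("--dialect", type = "character", default = "BED3"),
        opt("--out", type = "character", help = "output TSV [required]")),
      required = c("peaks", "rmsk", "genome", "out"))
  )
}

#' Command-line entry point
#'
#' Dispatches `simulate | density | profile | enrich` with their flags; a
#' thin executable script wrapping this function is installed under
#' `exec/recland`. Returns (rather than calls) the exit status so the
#' function is testable: 0 on success, 1 on a validation/computation
#' failure, 2 on a usage error.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status.
#' @export
recland_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  specs <- cli_specs()
  status <- tryCatch({
    if (length(argv) == 0L || !(argv[1L] %in% names(specs))) {
      stop(usage_error(paste0(
        "usage: recland <simulate|density|profile|enrich> [options]",
        if (length(argv)) paste0("\nunknown subcommand: ", argv[1L]) else "")))
    }
    sub <- argv[1L]
    spec <- specs[[sub]]
    common <- list(
      opt("--log-level", type = "character", default = "INFO", dest = "log_level"),
      opt("--threads", type = "integer", default = 1L,
          help = "accepted for interface compatibility; results are identical for any value"))
    parser <- optparse::OptionParser(option_list = c(spec$opts, common),
                                     prog = paste("recland", sub))
    parsed <- tryCatch(
      optparse::parse_args(parser, args = argv[-1L]),
      error = function(e) stop(usage_error(conditionMessage(e))),
      warning = function(w) stop(usage_error(conditionMessage(w))))
    for (req in spec$required) {
      if (is.null(parsed[[req]])) {
        stop(usage_error(paste0("missing required option --", gsub("_", "-", req))))
      }
    }
    old <- options(recland.log_level = parsed$log_level)
    on.exit(options(old), add = TRUE)
    switch(sub,
      simulate = stage_simulate(parsed$outdir, parsed$config, parsed$seed),
      density = stage_density(parsed$peaks, parsed$genes, parsed$expr,
                              parsed$genome, parsed$blacklist, parsed$out,
                              parsed$quantiles, parsed$mode, parsed$dialect),
      profile = stage_profile(parsed$recmap, parsed$genes, parsed$expr,
                              parsed$genome, parsed$out, parsed$classes,
                              parsed$window_width, parsed$bin_width,
                              parsed$max_dist),
      enrich = stage_enrich(parsed$peaks, parsed$rmsk, parsed$genome,
                            parsed$blacklist, parsed$zerocov, parsed$out,
                            min_zero_run = parsed$min_zero_run,
                            nperm = parsed$nperm, halfwidth = parsed$halfwidth,
                            seed = parsed$seed, dialect = parsed$dialect))
    0L
  },
  recland_usage_error = function(e) {
    message("recland: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("recland: error: ", conditionMessage(e))
    1L
  })
  status
}
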