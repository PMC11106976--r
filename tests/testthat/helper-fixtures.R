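# shared fixture builders; everything is generated in code at test time

# a small genome config that keeps simulation cheap in unit tests
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chroms = 1L, chrom_length = 2e6, n_genes = 20L,
               long_gene_fraction = 0.2, n_hotspots = 10L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# constant-value single-chromosome track
flat_track <- function(value, n_bins = 100, bin_size = 500, chrom = "chr1") {
  coverage_track(stats::setNames(list(rep(value, n_bins)), chrom), bin_size)
}

make_track <- function(values, bin_size = 500, chrom = "chr1") {
  coverage_track(stats::setNames(list(values), chrom), bin_size)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal gene table
gene_table <- function(chrom, start, end, strand = "+", name = NULL,
                       level = 1) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n),
             name = name %||% sprintf("g%02d", seq_len(n)),
             transcription_level = rep_len(level, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
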