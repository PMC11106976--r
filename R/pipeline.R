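#' Run the full synthetic-data pipeline
#'
#' Generates a miniature genome and the full set of synthetic experiments,
#' then runs every analysis stage in the order of the underlying study:
#' peak calling per S-phase timepoint, transience quantification,
#' directionality classification, breakpoint-overlap permutation testing
#' with BY correction, fragile-site genome-shuffle testing, ChIP
#' density-decline estimation, BrdU/Chr-RNA windowed correlation, and
#' elongation-rate estimation. Every stochastic stage draws from a stream
#' seeded deterministically from `config$seed` and the stage name, so a
#' rerun with the same config reproduces the bundle exactly.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, peaks (BED), truth tables
#'   (TSV), the SV table (TSV) and a JSON summary manifest are written there.
#' @param B resamples for the breakpoint permutation test.
#' @param shuffle_iterations iterations for the genome-shuffle test.
#' @param n_background,n_enriched rearrangement record counts.
#' @param elongation_rates named planted rates (kb/min); first is control.
#' @return list bundle with elements `genome`, `truth`, `peaks` (per
#'   timepoint), `transience`, `classes`, `categories`, `breakpoint_test`,
#'   `shuffle_test`, `decline`, `correlation`, `elongation`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = NULL,
                         B = 10000,
                         shuffle_iterations = 1000,
                         n_background = 300,
                         n_enriched = 60,
                         elongation_rates = c(DMSO = 2, DRB = 0.96,
                                              alphaAm = 1.34)) {
  genome <- simulate_genome(config)
  brdu <- simulate_brdu_timecourse(genome, config)
  s_tps <- config$timepoints[-1]

  peaks <- lapply(s_tps, function(tp) {
    call_peaks(brdu$tracks[[tp]]$sample, brdu$tracks[[tp]]$input,
               timepoint = tp)
  })
  names(peaks) <- s_tps

  norm <- lapply(config$timepoints, function(tp) {
    normalize_to_input(brdu$tracks[[tp]]$sample, brdu$tracks[[tp]]$input)
  })
  names(norm) <- config$timepoints
  transience <- peak_transience(peaks, norm[s_tps])

  first <- s_tps[1]
  classes <- classify_peaks(peaks[[first]], genome$genes,
                            genome$fork_directions)
  categories <- category_percentages(classes)

  svs <- simulate_rearrangements(brdu$truth, n_background, n_enriched, config)
  bw <- breakpoint_windows(svs)
  other_peaks <- do.call(rbind, lapply(peaks[-1], function(p)
    p[, c("chrom", "start", "end")]))
  bp_test <- if (nrow(peaks[[first]]) > 0 && nrow(other_peaks) > 0) {
    d_first <- closest_distance(peaks[[first]], bw)
    d_other <- closest_distance(other_peaks, bw)
    res <- permutation_test(d_first, d_other, B = B,
                            seed = stage_seed(config$seed, "permtest"))
    res$p_adjusted <- by_correction(res$p_value)
    res
  } else NULL

  fragile <- gintervals(brdu$truth$chrom[brdu$truth$enriched],
                        brdu$truth$start[brdu$truth$enriched],
                        brdu$truth$end[brdu$truth$enriched])
  shuffle_test <- if (nrow(bw) > 0 && nrow(fragile) > 0) {
    genome_shuffle_test(bw, fragile, sim_chrom_lengths(config),
                        iterations = shuffle_iterations,
                        seed = stage_seed(config$seed, "shuffle"))
  } else NULL

  chip <- simulate_chip_decline(genome, config, noise = TRUE)
  # density decline is measured over transcribed long genes (the decline is
  # transcription-dependent; untranscribed genes stay flat)
  decline <- density_decline(
    chip, genome$genes[genome$genes$transcription_level > 0, , drop = FALSE])

  chrrna <- simulate_chr_rna(genome, brdu$truth, config, noise = TRUE)
  correlation <- windowed_correlation(brdu$tracks[[first]]$sample, chrrna)

  tc <- simulate_timecourse(elongation_rates, config)
  elongation <- estimate_elongation(tc, control = names(elongation_rates)[1])

  manifest <- list(
    package_version = as.character(utils::packageVersion("forkstall")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "timepoints")],
    timepoints = config$timepoints,
    n_peaks = vapply(peaks, nrow, integer(1)),
    n_rearrangements = nrow(svs)
  )

  bundle <- list(genome = genome, truth = brdu$truth, peaks = peaks,
                 transience = transience, classes = classes,
                 categories = categories, breakpoint_test = bp_test,
                 shuffle_test = shuffle_test, decline = decline,
                 correlation = correlation, elongation = elongation,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir, svs, config)
  bundle
}

write_pipeline_outputs <- function(bundle, out_dir, svs, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(bundle$peaks)) {
    p <- bundle$peaks[[tp]]
    if (nrow(p) == 0) next
    safe <- gsub("[^A-Za-z0-9]+", "_", tp)
    write_bed(gintervals(p$chrom, p$start, p$end, name = p$name,
                         score = round(p$score * 10)),
              file.path(out_dir, paste0("peaks_", safe, ".bed")))
  }
  utils::write.table(bundle$truth, file.path(out_dir, "truth_hotspots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sv_table(svs, file.path(out_dir, "rearrangements.tsv"))
  summary <- list(
    manifest = bundle$manifest,
    categories = list(counts = as.list(bundle$categories$counts),
                      percent_in_gene = as.list(bundle$categories$percent_in_gene)),
    breakpoint_test = if (!is.null(bundle$breakpoint_test))
      bundle$breakpoint_test[c("t_star", "d_bar_a", "d_bar_b", "p_value",
                               "p_adjusted", "B")] else NULL,
    shuffle_test = if (!is.null(bundle$shuffle_test))
      bundle$shuffle_test[c("observed", "null_mean", "null_sd", "p_value",
                            "iterations")] else NULL,
    decline = bundle$decline[c("percent_reduction", "min_position", "n_genes")],
    correlation = bundle$correlation,
    elongation = lapply(bundle$elongation$conditions, function(e)
      e[c("mean_rate", "percent_reduction")])
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' End-to-end synthetic demo
#'
#' [run_pipeline()] on the default configuration with a chosen seed;
#' the whole run is deterministic given the seed.
#'
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @param ... passed to [run_pipeline()].
#' @export
forkstall_demo <- function(seed = 7, out_dir = NULL, ...) {
  run_pipeline(sim_config(seed = seed), out_dir = out_dir, ...)
}
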