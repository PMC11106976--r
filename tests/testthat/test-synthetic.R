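test_that("genome simulation is deterministic and respects n_genes = 0", {
  cfg <- small_config(seed = 3)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  cfg0 <- small_config(seed = 3, n_genes = 0L)
  g0 <- simulate_genome(cfg0)
  expect_equal(nrow(g0$genes), 0)
  expect_length(g0$fork_directions, 0)
})

test_that("placed genes never overlap and stay on the chromosome", {
  for (s in 1:3) {
    g <- simulate_genome(sim_config(seed = s))$genes
    expect_true(all(g$start >= 0 & g$end <= 10e6))
    for (ch in unique(g$chrom)) {
      d <- g[g$chrom == ch, ]
      d <- d[order(d$start), ]
      expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
    }
  }
})

test_that("full codirectionality forces rightward forks on plus-strand genes", {
  cfg <- small_config(seed = 5, p_undetermined = 0,
                      fraction_codirectional = 1)
  g <- simulate_genome(cfg)$genes
  expect_true(all(g$fork_direction[g$strand == "+"] == "rightward"))
  expect_true(all(g$fork_direction[g$strand == "-"] == "leftward"))
})

test_that("planted hotspots lie inside replication domains of their timepoint", {
  cfg <- small_config(seed = 2)
  g <- simulate_genome(cfg)
  b <- simulate_brdu_timecourse(g, cfg)
  expect_equal(nrow(b$truth), cfg$n_hotspots)
  for (i in seq_len(nrow(b$truth))) {
    d <- g$program[g$program$chrom == b$truth$chrom[i] &
                     g$program$start <= b$truth$center[i] &
                     g$program$end > b$truth$center[i], ]
    expect_equal(d$timepoint, b$truth$timepoint[i])
  }
  # no hotspot in the pre-replicative timepoint
  expect_false(cfg$timepoints[1] %in% b$truth$timepoint)
})

test_that("truth directionality classes match classify_peaks on truth coordinates", {
  cfg <- sim_config(seed = 4)
  g <- simulate_genome(cfg)
  b <- simulate_brdu_timecourse(g, cfg)
  cls <- classify_peaks(gintervals(b$truth$chrom, b$truth$start, b$truth$end),
                        g$genes, g$fork_directions)
  expect_equal(as.character(cls$class), as.character(b$truth$class))
})

test_that("hotspot bins follow the stated Poisson mixture mean", {
  # amplitude 10, occupancy 0.5, depth 30 -> mean 30 * (1 + 0.5 * 9) = 165
  cfg <- small_config(seed = 6, hotspot_occupancy = 0.5,
                      hotspot_amplitude = 10, read_depth = 30)
  g <- simulate_genome(cfg)
  vals <- unlist(lapply(1:20, function(s) {
    cfg2 <- small_config(seed = 100 + s, hotspot_occupancy = 0.5,
                         hotspot_amplitude = 10, read_depth = 30)
    g2 <- simulate_genome(cfg2)
    b <- simulate_brdu_timecourse(g2, cfg2)
    unlist(lapply(seq_len(nrow(b$truth)), function(i) {
      tr <- b$tracks[[b$truth$timepoint[i]]]$sample
      b0 <- floor(b$truth$start[i] / cfg2$bin_size) + 1
      b1 <- ceiling(b$truth$end[i] / cfg2$bin_size)
      tr$bins[[b$truth$chrom[i]]][b0:b1]
    }))
  }))
  expect_equal(mean(vals), 165, tolerance = 0.02)
})

test_that("hotspots are transient: elevated in their own timepoint only", {
  # Monte-Carlo over simulations: mean normalized signal at a hotspot is
  # strictly higher in its own timepoint than in the following one
  n_higher <- 0; n_tot <- 0
  for (s in 1:20) {
    cfg <- small_config(seed = 200 + s)
    g <- simulate_genome(cfg)
    b <- simulate_brdu_timecourse(g, cfg)
    stps <- cfg$timepoints[-1]
    for (i in seq_len(nrow(b$truth))) {
      ti <- match(b$truth$timepoint[i], stps)
      if (is.na(ti) || ti == length(stps)) next
      iv <- data.frame(chrom = b$truth$chrom[i], start = b$truth$start[i],
                       end = b$truth$end[i])
      own <- quantify_at_intervals(
        normalize_to_input(b$tracks[[stps[ti]]]$sample,
                           b$tracks[[stps[ti]]]$input), iv)
      nxt <- quantify_at_intervals(
        normalize_to_input(b$tracks[[stps[ti + 1]]]$sample,
                           b$tracks[[stps[ti + 1]]]$input), iv)
      n_tot <- n_tot + 1
      if (own > nxt) n_higher <- n_higher + 1
    }
  }
  expect_gt(n_tot, 50)
  expect_gt(n_higher / n_tot, 0.95)
})

test_that("expected sample mass follows the occupancy/amplitude closed form", {
  cfg <- sim_config(seed = 9)
  g <- simulate_genome(cfg)
  b <- simulate_brdu_timecourse(g, cfg)
  tp <- cfg$timepoints[2]
  n_bins <- cfg$n_chroms * cfg$chrom_length / cfg$bin_size
  hot <- b$truth[b$truth$timepoint == tp, ]
  hot_bins <- sum(ceiling(hot$end / cfg$bin_size) -
                    floor(hot$start / cfg$bin_size))
  expected <- cfg$read_depth *
    (n_bins + hot_bins * cfg$hotspot_occupancy * (cfg$hotspot_amplitude - 1))
  expect_equal(library_size(b$tracks[[tp]]$sample), expected, tolerance = 0.01)
})

test_that("chromatin RNA track shows twin accumulations flanking hotspots", {
  cfg <- sim_config(seed = 10)
  g <- simulate_genome(cfg)
  b <- simulate_brdu_timecourse(g, cfg)
  rna <- simulate_chr_rna(g, b$truth, cfg)  # noise-free expectation
  in_gene <- b$truth[!is.na(b$truth$host_gene), ]
  expect_gt(nrow(in_gene), 3)
  prof <- profile_at_anchors(rna, gintervals(in_gene$chrom, in_gene$start,
                                             in_gene$end), flank = 4000)
  ic <- which.min(abs(prof$position))
  left <- prof$mean[prof$position < -1000]
  right <- prof$mean[prof$position > 1000]
  # two flanking maxima above the center dip
  expect_gt(max(left), prof$mean[ic])
  expect_gt(max(right), prof$mean[ic])
})

test_that("zero-expression genes contribute no chromatin RNA signal", {
  cfg <- small_config(seed = 11, transcribed_fraction = 1e-9)
  g <- simulate_genome(cfg)
  b <- simulate_brdu_timecourse(g, cfg)
  rna <- simulate_chr_rna(g, b$truth, cfg)
  expect_equal(library_size(rna), 0)
})

test_that("strand-restricted chromatin RNA only covers genes of that strand", {
  cfg <- small_config(seed = 12)
  g <- simulate_genome(cfg)
  b <- simulate_brdu_timecourse(g, cfg)
  plus <- simulate_chr_rna(g, b$truth, cfg, strand = "+")
  minus_genes <- g$genes[g$genes$strand == "-" & g$genes$transcription_level > 0, ]
  vals <- quantify_at_intervals(plus, minus_genes)
  # minus-strand gene bodies carry only spill-over from hotspot bumps, not
  # body signal; most should be zero
  expect_lt(stats::median(vals), 1e-9)
})

test_that("planted ChIP decline has the planted magnitude and position", {
  cfg <- sim_config(seed = 13, decline_percent = 17.2)
  g <- simulate_genome(cfg)
  chip <- simulate_chip_decline(g, cfg)  # noise-free
  long_tx <- g$genes[g$genes$transcription_level > 0 &
                       (g$genes$end - g$genes$start) > 100e3, ]
  # noise-free track value at TSS + 75 kb is 0.828 * baseline
  i <- which(long_tx$strand == "+")[1]
  gene <- long_tx[i, ]
  v <- quantify_at_intervals(chip, data.frame(chrom = gene$chrom,
                                              start = gene$start + 74750,
                                              end = gene$start + 75250))
  expect_equal(v, 0.828 * cfg$read_depth, tolerance = 0.01)
  # upstream of the TSS the signal is flat at baseline for all genes
  up <- quantify_at_intervals(chip, data.frame(chrom = g$genes$chrom,
                                               start = pmax(0, g$genes$start - 5000),
                                               end = pmax(1, g$genes$start - 4000)))
  expect_true(all(abs(up - cfg$read_depth) < 1e-6 | is.na(up)))
})

test_that("decline_percent = 0 gives a flat expectation", {
  cfg <- sim_config(seed = 14, decline_percent = 0)
  g <- simulate_genome(cfg)
  chip <- simulate_chip_decline(g, cfg)
  expect_true(all(vapply(chip$bins, function(v) all(v == cfg$read_depth),
                         logical(1))))
})

test_that("rearrangement counts and enrichment placement are honoured", {
  cfg <- sim_config(seed = 15)
  g <- simulate_genome(cfg)
  b <- simulate_brdu_timecourse(g, cfg)
  sv <- simulate_rearrangements(b$truth, n_background = 40, n_enriched = 25, cfg)
  expect_equal(nrow(sv), 65)
  # all-enriched records overlap the enriched hotspot subset
  sv2 <- simulate_rearrangements(b$truth, n_background = 0, n_enriched = 30, cfg)
  enr <- gintervals(b$truth$chrom[b$truth$enriched],
                    b$truth$start[b$truth$enriched],
                    b$truth$end[b$truth$enriched])
  bw <- breakpoint_windows(sv2)
  # each record contributed one placed breakpoint inside a hotspot
  d <- closest_distance(bw, enr)
  placed_overlaps <- sum(d == 0)
  expect_gte(placed_overlaps, 30)
})

test_that("background-only breakpoints overlap hotspots at the genomic rate", {
  cfg <- sim_config(seed = 16)
  g <- simulate_genome(cfg)
  b <- simulate_brdu_timecourse(g, cfg)
  sv <- simulate_rearrangements(b$truth, n_background = 2000, n_enriched = 0, cfg)
  bw <- breakpoint_windows(sv)
  hot <- gintervals(b$truth$chrom, b$truth$start, b$truth$end)
  frac <- overlap_fraction(closest_distance(bw, hot))
  # binomial expectation: (hotspot + window) footprint over the genome
  p_exp <- sum(b$truth$end - b$truth$start + 500) / (2 * 10e6)
  expect_equal(frac, p_exp, tolerance = 0.25)
})

test_that("timecourse recovery reflects planted arrival times", {
  tc <- simulate_timecourse(c(ctrl = 2), sim_config(seed = 17))
  # rate 2 kb/min, primer 40 kb: front arrives at 20 min
  d <- tc[tc$primer_kb == 40, ]
  expect_equal(d$level[d$time_min == 20], 1)
  expect_lt(d$level[d$time_min == 10], 1)
  # effectively infinite rate: plateau from the first sample on
  tc2 <- simulate_timecourse(c(fast = 1e6), sim_config(seed = 17))
  expect_true(all(tc2$level[tc2$time_min > 0] == 1))
})
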