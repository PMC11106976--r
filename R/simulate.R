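#' Simulation configuration
#'
#' Builds the parameter set for the miniature-genome generators. Defaults
#' describe a desk-scale genome (2 chromosomes x 10 Mb, 150 genes, 500-bp
#' bins) with the six cell-cycle timepoints of a synchronised S-phase
#' timecourse, mean read depth 30 per bin, and transient stalling hotspots
#' present in half the cells at 10-fold enrichment.
#'
#' @param seed integer seed driving all generators.
#' @param n_chroms,chrom_length genome shape; `chrom_length` must be a
#'   multiple of `bin_size`.
#' @param bin_size track bin width in bp.
#' @param n_genes number of non-overlapping genes to place.
#' @param long_gene_fraction fraction of genes drawn from the long (>100 kb)
#'   length component.
#' @param long_gene_range bp range of the long component (uniform).
#' @param short_gene_meanlog,short_gene_sdlog log-normal parameters of the
#'   short component (bp).
#' @param transcribed_fraction fraction of genes with nonzero expression.
#' @param timepoints ordered labels; the first is taken as pre-replicative
#'   (G1/S), the rest as S-phase timepoints that replicate DNA.
#' @param timepoint_weights probability that a replication domain is
#'   replicated at each S-phase timepoint (early-skewed by default).
#' @param domain_size replication-timing domain width in bp.
#' @param read_depth mean reads per bin.
#' @param n_hotspots number of planted stalling hotspots.
#' @param hotspot_width hotspot width in bp.
#' @param hotspot_occupancy fraction of cells stalled at a hotspot (0-1].
#' @param hotspot_amplitude fold enrichment in stalled cells.
#' @param enriched_hotspot_fraction fraction of hotspots designated
#'   breakpoint-enriched in the truth table.
#' @param p_undetermined probability a transcribed gene is replicated by
#'   forks from both ends.
#' @param fraction_codirectional among genes with a single fork direction,
#'   probability that the fork is codirectional with transcription.
#' @param decline_percent planted ChIP density reduction (%) over long
#'   transcribed genes.
#' @param decline_min_pos bp downstream of the TSS where the planted ChIP
#'   density minimum sits.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 10e6,
                       bin_size = 500,
                       n_genes = 150L,
                       long_gene_fraction = 0.25,
                       long_gene_range = c(100e3, 250e3),
                       short_gene_meanlog = log(20e3),
                       short_gene_sdlog = 0.45,
                       transcribed_fraction = 0.8,
                       timepoints = c("G1/S", "Early S", "Early/Mid S",
                                      "Mid S", "Mid/Late S", "Late S/G2"),
                       timepoint_weights = c(0.30, 0.25, 0.20, 0.15, 0.10),
                       domain_size = 500e3,
                       read_depth = 30,
                       n_hotspots = 80L,
                       hotspot_width = 2000,
                       hotspot_occupancy = 0.5,
                       hotspot_amplitude = 10,
                       enriched_hotspot_fraction = 0.25,
                       p_undetermined = 0.30,
                       fraction_codirectional = 0.5,
                       decline_percent = 17.2,
                       decline_min_pos = 75e3) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms >= 1, cfg$n_genes >= 0, cfg$bin_size >= 1,
            cfg$chrom_length %% cfg$bin_size == 0,
            cfg$hotspot_occupancy >= 0, cfg$hotspot_occupancy <= 1,
            length(cfg$timepoints) >= 2,
            length(cfg$timepoint_weights) == length(cfg$timepoints) - 1)
  cfg$timepoint_weights <- cfg$timepoint_weights / sum(cfg$timepoint_weights)
  class(cfg) <- "sim_config"
  cfg
}

sim_chrom_names <- function(config) paste0("chr", seq_len(config$n_chroms))

sim_chrom_lengths <- function(config) {
  stats::setNames(rep(config$chrom_length, config$n_chroms),
                  sim_chrom_names(config))
}

#' Simulate a miniature genome annotation
#'
#' Places non-overlapping genes with random strands, log-normal expression
#' levels, a replication-timing program (contiguous domains assigned to
#' S-phase timepoints, skewed towards early S), and a replication-fork
#' direction per gene. Transcribed genes are `both`-direction (replicated
#' from both ends) with probability `p_undetermined`; otherwise codirectional
#' with transcription with probability `fraction_codirectional`, emulating
#' origin placement near the TSS of long transcribed genes.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (a data frame: chrom, start, end, strand, name,
#'   transcription_level, replicated_timepoint, fork_direction),
#'   `fork_directions` (named character vector gene -> direction in
#'   rightward/leftward/both), and `program` (domain data frame: chrom,
#'   start, end, timepoint).
#' @export
simulate_genome <- function(config) {
  with_seed(stage_seed(config$seed, "genome"), {
    chroms <- sim_chrom_names(config)
    # replication-timing domains
    s_tp <- config$timepoints[-1]
    prog <- do.call(rbind, lapply(chroms, function(ch) {
      starts <- seq(0, config$chrom_length - 1, by = config$domain_size)
      data.frame(chrom = ch, start = starts,
                 end = pmin(starts + config$domain_size, config$chrom_length),
                 timepoint = sample(s_tp, length(starts), replace = TRUE,
                                    prob = config$timepoint_weights),
                 stringsAsFactors = FALSE)
    }))
    if (config$n_genes == 0) {
      genes <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), strand = character(),
                          name = character(), transcription_level = numeric(),
                          replicated_timepoint = character(),
                          fork_direction = character(),
                          stringsAsFactors = FALSE)
      return(list(genes = genes,
                  fork_directions = stats::setNames(character(), character()),
                  program = prog))
    }
    n_long <- round(config$n_genes * config$long_gene_fraction)
    lens <- c(stats::runif(n_long, config$long_gene_range[1],
                           config$long_gene_range[2]),
              stats::rlnorm(config$n_genes - n_long, config$short_gene_meanlog,
                            config$short_gene_sdlog))
    lens <- round(pmax(lens, 2 * config$bin_size))
    lens <- sample(lens)
    # spread genes over chromosomes, then place with random (stick-broken) gaps
    chrom_of <- sample(rep(chroms, length.out = config$n_genes))
    rows <- list()
    for (ch in chroms) {
      l <- lens[chrom_of == ch]
      if (length(l) == 0) next
      free <- config$chrom_length - sum(l)
      if (free < 0)
        stop("gene placement capacity error: total gene length exceeds chromosome")
      g <- stats::rexp(length(l) + 1)
      gaps <- floor(free * g / sum(g))
      starts <- cumsum(gaps[-length(gaps)] + c(0, l[-length(l)]))
      rows[[ch]] <- data.frame(chrom = ch, start = starts, end = starts + l,
                               stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    n <- nrow(genes)
    genes$strand <- sample(c("+", "-"), n, replace = TRUE)
    genes$name <- sprintf("gene%03d", seq_len(n))
    transcribed <- stats::runif(n) < config$transcribed_fraction
    genes$transcription_level <- ifelse(transcribed,
                                        stats::rlnorm(n, meanlog = 1, sdlog = 1), 0)
    # replicated timepoint = timing domain of the TSS
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
    genes$replicated_timepoint <- vapply(seq_len(n), function(i) {
      d <- prog[prog$chrom == genes$chrom[i] & prog$start <= tss[i] &
                  prog$end > tss[i], ]
      d$timepoint[1]
    }, character(1))
    # fork direction relative to transcription
    both <- stats::runif(n) < config$p_undetermined
    codir <- stats::runif(n) < config$fraction_codirectional
    dir_codir <- ifelse(genes$strand == "+", "rightward", "leftward")
    dir_headon <- ifelse(genes$strand == "+", "leftward", "rightward")
    genes$fork_direction <- ifelse(both, "both",
                                   ifelse(codir, dir_codir, dir_headon))
    rownames(genes) <- NULL
    list(genes = genes,
         fork_directions = stats::setNames(genes$fork_direction, genes$name),
         program = prog)
  })
}

#' Simulate a multi-timepoint BrdU-Seq experiment
#'
#' Produces one (sample, input) pair of Poisson coverage tracks per timepoint
#' and a ground-truth table of planted hotspots. The input is
#' Poisson(`read_depth`) in every bin; the sample is the same except at
#' hotspot bins in the hotspot's own timepoint, where the Poisson mean is
#' `read_depth * (1 + occupancy * (amplitude - 1))` — the expected signal of
#' a cell population in which a fraction `occupancy` of cells carries
#' `amplitude`-fold local enrichment. Hotspots are transient: elevated in
#' exactly one timepoint. Each hotspot lies inside a replication domain of
#' its own timepoint; the first (pre-replicative) timepoint receives no
#' hotspots.
#'
#' @param genome a [simulate_genome()] result (or list with `genes` and
#'   `program`).
#' @param config a [sim_config()].
#' @return list with `tracks` (per timepoint: list(sample, input) of
#'   [coverage_track()]), and `truth` (data frame: chrom, start, end, center,
#'   timepoint, host_gene, class, enriched).
#' @export
simulate_brdu_timecourse <- function(genome, config) {
  genes <- genome$genes
  prog <- genome$program
  with_seed(stage_seed(config$seed, "brdu"), {
    n_bins <- config$chrom_length / config$bin_size
    chroms <- sim_chrom_names(config)
    w_bins <- max(1L, round(config$hotspot_width / config$bin_size))
    # place hotspots at non-overlapping positions, timepoint from the domain
    centers <- data.frame(chrom = sample(chroms, config$n_hotspots, replace = TRUE),
                          pos = NA_real_, stringsAsFactors = FALSE)
    for (ch in chroms) {
      k <- sum(centers$chrom == ch)
      if (k == 0) next
      # sample start bins with at least one hotspot-width spacing
      avail <- seq(2L, n_bins - w_bins - 1L)
      pos <- sort(sample(avail, k))
      while (k > 1 && any(diff(pos) < 2 * w_bins)) {
        pos <- sort(sample(avail, k))
      }
      centers$pos[centers$chrom == ch] <- (pos + w_bins / 2) * config$bin_size
    }
    start <- centers$pos - config$hotspot_width / 2
    truth <- data.frame(chrom = centers$chrom,
                        start = start,
                        end = start + config$hotspot_width,
                        center = centers$pos,
                        stringsAsFactors = FALSE)
    truth$timepoint <- vapply(seq_len(nrow(truth)), function(i) {
      d <- prog[prog$chrom == truth$chrom[i] & prog$start <= truth$center[i] &
                  prog$end > truth$center[i], ]
      d$timepoint[1]
    }, character(1))
    cls <- classify_peaks(
      gintervals(truth$chrom, truth$start, truth$end),
      genes, genome$fork_directions)
    truth$host_gene <- cls$gene
    truth$class <- cls$class
    # breakpoint-enriched subset: drawn from the earliest S timepoint's
    # hotspots (early-S stalling sites are the fragile ones)
    truth$enriched <- FALSE
    n_enr <- round(nrow(truth) * config$enriched_hotspot_fraction)
    pool <- which(truth$timepoint == config$timepoints[2])
    if (length(pool) == 0) pool <- seq_len(nrow(truth))
    n_enr <- min(n_enr, length(pool))
    if (n_enr > 0) truth$enriched[sample(pool, n_enr)] <- TRUE

    hot_mean <- config$read_depth *
      (1 + config$hotspot_occupancy * (config$hotspot_amplitude - 1))
    tracks <- lapply(config$timepoints, function(tp) {
      input <- lapply(chroms, function(ch) stats::rpois(n_bins, config$read_depth))
      names(input) <- chroms
      smp <- lapply(chroms, function(ch) stats::rpois(n_bins, config$read_depth))
      names(smp) <- chroms
      sel <- which(truth$timepoint == tp)
      for (i in sel) {
        ch <- truth$chrom[i]
        b0 <- floor(truth$start[i] / config$bin_size) + 1
        b1 <- ceiling(truth$end[i] / config$bin_size)
        smp[[ch]][b0:b1] <- stats::rpois(b1 - b0 + 1, hot_mean)
      }
      list(sample = coverage_track(smp, config$bin_size),
           input = coverage_track(input, config$bin_size))
    })
    names(tracks) <- config$timepoints
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate a chromatin-bound RNA track
#'
#' Expected signal is proportional to each transcribed gene's expression
#' level along its body, modulated around planted in-gene hotspot centers by
#' twin Gaussian accumulations flanking the center and a dip at the center
#' itself (nascent transcription piles up on both sides of a stalling site).
#'
#' @param genome a [simulate_genome()] result.
#' @param truth hotspot truth table from [simulate_brdu_timecourse()].
#' @param config a [sim_config()].
#' @param noise add Poisson noise around the expectation (default FALSE:
#'   return the noise-free expectation).
#' @param strand `"both"` (sum), `"+"` or `"-"`: restrict to genes on one
#'   strand.
#' @param bump_offset,bump_sd,bump_height,dip_sd,dip_depth shape parameters
#'   (bp / relative units) of the twin-accumulation profile.
#' @return a [coverage_track()].
#' @export
simulate_chr_rna <- function(genome, truth, config, noise = FALSE,
                             strand = "both", bump_offset = 2000,
                             bump_sd = 800, bump_height = 2, dip_sd = 600,
                             dip_depth = 0.5) {
  genes <- genome$genes
  n_bins <- config$chrom_length / config$bin_size
  chroms <- sim_chrom_names(config)
  bins <- lapply(chroms, function(ch) numeric(n_bins))
  names(bins) <- chroms
  keep <- genes$transcription_level > 0
  if (strand %in% c("+", "-")) keep <- keep & genes$strand == strand
  gsel <- genes[keep, , drop = FALSE]
  bs <- config$bin_size
  for (i in seq_len(nrow(gsel))) {
    b0 <- floor(gsel$start[i] / bs) + 1
    b1 <- ceiling(gsel$end[i] / bs)
    bins[[gsel$chrom[i]]][b0:b1] <- bins[[gsel$chrom[i]]][b0:b1] +
      gsel$transcription_level[i]
  }
  # hotspot modulation: twin bumps +- offset, dip at center
  in_gene <- truth[!is.na(truth$host_gene) &
                     truth$host_gene %in% gsel$name, , drop = FALSE]
  for (i in seq_len(nrow(in_gene))) {
    ch <- in_gene$chrom[i]
    level <- gsel$transcription_level[match(in_gene$host_gene[i], gsel$name)]
    span <- 3 * (bump_offset + 3 * bump_sd)
    b0 <- max(1, floor((in_gene$center[i] - span) / bs) + 1)
    b1 <- min(n_bins, ceiling((in_gene$center[i] + span) / bs))
    d <- (b0:b1 - 0.5) * bs - in_gene$center[i]
    mod <- bump_height * level *
      (exp(-(d - bump_offset)^2 / (2 * bump_sd^2)) +
         exp(-(d + bump_offset)^2 / (2 * bump_sd^2))) -
      dip_depth * level * exp(-d^2 / (2 * dip_sd^2))
    bins[[ch]][b0:b1] <- pmax(0, bins[[ch]][b0:b1] + mod)
  }
  if (noise) {
    bins <- with_seed(stage_seed(config$seed, "chrrna"), {
      lapply(bins, function(v) stats::rpois(length(v), v))
    })
  }
  coverage_track(bins, bs)
}

#' Simulate a replication-factor ChIP track with a planted density decline
#'
#' Expected signal is flat at `read_depth` genome-wide. Along each
#' transcribed gene longer than 100 kb the expectation declines linearly
#' from baseline at the TSS to `baseline * (1 - decline_percent/100)` at
#' `decline_min_pos` bp downstream (75 kb by default), then partially
#' recovers (linearly, at half the decline slope, capped halfway back to
#' baseline) — the shape of a replication-fork component that travels faster
#' through the transcribed gene body and of replication-coupled histone
#' density. Untranscribed and short genes stay flat.
#'
#' @param genome a [simulate_genome()] result.
#' @param config a [sim_config()]; uses `decline_percent`,
#'   `decline_min_pos`, `read_depth`.
#' @param noise add Poisson noise (default FALSE).
#' @param min_gene_length only genes longer than this get the decline.
#' @return a [coverage_track()].
#' @export
simulate_chip_decline <- function(genome, config, noise = FALSE,
                                  min_gene_length = 100e3) {
  genes <- genome$genes
  bs <- config$bin_size
  n_bins <- config$chrom_length / bs
  chroms <- sim_chrom_names(config)
  baseline <- config$read_depth
  dp <- config$decline_percent / 100
  mpos <- config$decline_min_pos
  bins <- lapply(chroms, function(ch) rep(baseline, n_bins))
  names(bins) <- chroms
  sel <- genes$transcription_level > 0 & (genes$end - genes$start) > min_gene_length
  for (i in which(sel)) {
    b0 <- floor(genes$start[i] / bs) + 1
    b1 <- ceiling(genes$end[i] / bs)
    pos <- (b0:b1 - 0.5) * bs
    d <- if (genes$strand[i] == "+") pos - genes$start[i] else genes$end[i] - pos
    # linear decline to the minimum, then linear half-slope recovery capped
    # halfway back to baseline
    f <- ifelse(d <= mpos,
                1 - dp * d / mpos,
                pmin(1 - dp / 2, 1 - dp + (dp / 2) * (d - mpos) / mpos))
    f[d < 0] <- 1
    bins[[genes$chrom[i]]][b0:b1] <- baseline * f
  }
  if (noise) {
    bins <- with_seed(stage_seed(config$seed, "chip"), {
      lapply(bins, function(v) stats::rpois(length(v), v))
    })
  }
  coverage_track(bins, bs)
}

#' Simulate structural-rearrangement records
#'
#' `n_background` records get their primary breakpoint uniform over the
#' genome; `n_enriched` records get it uniform inside the truth table's
#' breakpoint-enriched hotspot subset. Every record's mate breakpoint is
#' placed independently and uniformly. Breakpoint windows are
#' `window_width` bp wide.
#'
#' @param truth hotspot truth table from [simulate_brdu_timecourse()].
#' @param n_background,n_enriched record counts.
#' @param config a [sim_config()].
#' @param window_width breakpoint window width in bp.
#' @return a `rearrangements` data frame (0-based half-open windows).
#' @export
simulate_rearrangements <- function(truth, n_background, n_enriched, config,
                                    window_width = 500) {
  with_seed(stage_seed(config$seed, "sv"), {
    chroms <- sim_chrom_names(config)
    L <- config$chrom_length
    rand_bp <- function(n) {
      data.frame(chrom = sample(chroms, n, replace = TRUE),
                 pos = floor(stats::runif(n, 0, L - window_width)),
                 stringsAsFactors = FALSE)
    }
    enr <- truth[truth$enriched, , drop = FALSE]
    if (n_enriched > 0 && nrow(enr) == 0)
      stop("truth table has no breakpoint-enriched hotspots")
    primary <- rand_bp(n_background)
    if (n_enriched > 0) {
      idx <- sample(nrow(enr), n_enriched, replace = TRUE)
      inpos <- floor(enr$start[idx] +
                       stats::runif(n_enriched) * (enr$end[idx] - enr$start[idx] - window_width))
      primary <- rbind(primary,
                       data.frame(chrom = enr$chrom[idx], pos = pmax(0, inpos),
                                  stringsAsFactors = FALSE))
    }
    n <- nrow(primary)
    if (n == 0) {
      out <- data.frame(id = character(), chrom_l = character(),
                        start_l = numeric(), end_l = numeric(),
                        chrom_r = character(), start_r = numeric(),
                        end_r = numeric(), sv_class = character(),
                        stringsAsFactors = FALSE)
      class(out) <- c("rearrangements", "data.frame")
      return(out)
    }
    mate <- rand_bp(n)
    swap <- primary$chrom == mate$chrom & primary$pos > mate$pos |
      primary$chrom > mate$chrom
    l <- ifelse(swap, mate$chrom, primary$chrom)
    lp <- ifelse(swap, mate$pos, primary$pos)
    r <- ifelse(swap, primary$chrom, mate$chrom)
    rp <- ifelse(swap, primary$pos, mate$pos)
    out <- data.frame(
      id = sprintf("sv%04d", seq_len(n)),
      chrom_l = l, start_l = lp, end_l = lp + window_width,
      chrom_r = r, start_r = rp, end_r = rp + window_width,
      sv_class = sample(c("deletion", "inversion", "translocation", "other"),
                        n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    class(out) <- c("rearrangements", "data.frame")
    out
  })
}

#' Simulate a DRB-release pre-mRNA recovery timecourse
#'
#' After release from a transcription-initiation block, the polymerase front
#' travels at the condition's elongation rate; the pre-mRNA level at a primer
#' rises to the control plateau as the front passes. Cells lose a little
#' synchrony after release, so the population-level signal is modeled as a
#' linear rise over `rise` minutes (two sampling intervals by default)
#' ending at the arrival time (`primer_position / rate`), sampled every
#' `sampling_interval` minutes starting at release (t = 0).
#'
#' @param rates named numeric vector of planted elongation rates (kb/min) per
#'   condition; the first element is taken as the control.
#' @param config a [sim_config()] (for the seed).
#' @param primer_positions_kb primer distances from the TSS in kb.
#' @param sampling_interval minutes between lysed dishes.
#' @param rise minutes over which the population signal climbs from 0 to
#'   plateau (desynchronization width).
#' @param t_max last sample time (default: enough for the slowest condition
#'   to pass the furthest primer, plus the rise).
#' @param noise_sd Gaussian measurement noise on the normalized level.
#' @return data frame: condition, primer_kb, time_min, level (class
#'   `recovery_timecourse`).
#' @export
simulate_timecourse <- function(rates, config = sim_config(),
                                primer_positions_kb = c(1, 15, 40, 60, 80),
                                sampling_interval = 10,
                                rise = 2 * sampling_interval,
                                t_max = NULL, noise_sd = 0) {
  stopifnot(!is.null(names(rates)), all(rates > 0))
  if (is.null(t_max)) {
    t_max <- ceiling((max(primer_positions_kb) / min(rates) + rise) /
                       sampling_interval) * sampling_interval
  }
  times <- seq(0, t_max, by = sampling_interval)
  grid <- expand.grid(condition = names(rates), primer_kb = primer_positions_kb,
                      time_min = times, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  arrival <- grid$primer_kb / rates[grid$condition]
  level <- pmin(1, pmax(0, 1 + (grid$time_min - arrival) / rise))
  if (noise_sd > 0) {
    level <- with_seed(stage_seed(config$seed, "timecourse"), {
      pmax(0, level + stats::rnorm(length(level), 0, noise_sd))
    })
  }
  grid$level <- level
  grid <- grid[order(grid$condition, grid$primer_kb, grid$time_min), ]
  rownames(grid) <- NULL
  class(grid) <- c("recovery_timecourse", "data.frame")
  grid
}
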