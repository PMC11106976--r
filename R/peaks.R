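#' Normalize a sample track to its input
#'
#' Bin-wise ratio of depth-scaled sample to depth-scaled input with a
#' pseudocount: `(s' + pc) / (i' + pc)` where each track is divided by its
#' library size and multiplied by the mean library size of the pair. With
#' `pseudocount = 0` the operation is invariant to rescaling both tracks by
#' a common factor.
#'
#' @param sample,input [coverage_track()]s with matching bins.
#' @param pseudocount added to numerator and denominator after depth
#'   scaling (default 1).
#' @return a [coverage_track()] of enrichment ratios.
#' @export
normalize_to_input <- function(sample, input, pseudocount = 1) {
  check_compatible(sample, input)
  ls_s <- library_size(sample)
  ls_i <- library_size(input)
  mean_ls <- (ls_s + ls_i) / 2
  f_s <- if (ls_s > 0) mean_ls / ls_s else 1
  f_i <- if (ls_i > 0) mean_ls / ls_i else 1
  bins <- lapply(track_chroms(sample), function(ch) {
    (sample$bins[[ch]] * f_s + pseudocount) /
      (input$bins[[ch]] * f_i + pseudocount)
  })
  names(bins) <- track_chroms(sample)
  coverage_track(bins, sample$bin_size)
}

#' Call enrichment peaks with a Poisson local-background model
#'
#' For each bin the local Poisson rate is the maximum of the input track's
#' mean over a 1-kb window, a 10-kb window, and the genome-wide background
#' (all centred on the bin), after scaling both libraries to their common
#' mean depth. Bins with Poisson upper-tail probability
#' `P(X >= sample) < p_threshold` and fold enrichment `>= min_fold` are kept
#' and merged when separated by at most `max_gap` bp. The summit is the
#' center of the maximum-signal bin.
#'
#' @param sample,input [coverage_track()]s with matching bins.
#' @param p_threshold Poisson tail threshold (default 1e-5).
#' @param min_fold minimum fold enrichment over the local rate (default 2).
#' @param max_gap merge distance in bp (default 1000).
#' @param timepoint optional label stored with each peak.
#' @param scale_libraries scale both tracks to their mean library size
#'   before testing (default TRUE; a no-op for equal-depth libraries).
#' @return a [gintervals()] data frame with extra columns `summit`, `score`
#'   (-log10 p), `fold_enrichment`, `timepoint`; zero rows when nothing
#'   passes.
#' @export
call_peaks <- function(sample, input, p_threshold = 1e-5, min_fold = 2,
                       max_gap = 1000, timepoint = NA_character_,
                       scale_libraries = TRUE) {
  check_compatible(sample, input)
  bs <- sample$bin_size
  if (scale_libraries) {
    ls_s <- library_size(sample); ls_i <- library_size(input)
    mean_ls <- (ls_s + ls_i) / 2
    f_s <- if (ls_s > 0) mean_ls / ls_s else 1
    f_i <- if (ls_i > 0) mean_ls / ls_i else 1
  } else {
    f_s <- f_i <- 1
  }
  genome_bg <- if (library_size(input) > 0) {
    f_i * library_size(input) / sum(lengths(input$bins))
  } else 0
  out <- list()
  for (ch in track_chroms(sample)) {
    s <- sample$bins[[ch]] * f_s
    v <- input$bins[[ch]] * f_i
    if (length(s) == 0) next
    k1 <- max(1L, round(1000 / bs))
    k10 <- max(1L, round(10000 / bs))
    lambda <- pmax(moving_average(v, k1), moving_average(v, k10), genome_bg)
    # P(Pois(lambda) >= s) via the gamma identity; continuous in s
    p <- ifelse(s <= 0, 1, stats::pgamma(lambda, shape = s, lower.tail = TRUE))
    fold <- ifelse(lambda > 0, s / lambda, Inf)
    sig <- which(p < p_threshold & fold >= min_fold & lambda > 0)
    if (length(sig) == 0) next
    gap_bins <- max(1L, floor(max_gap / bs))
    brk <- c(0, which(diff(sig) > gap_bins), length(sig))
    for (j in seq_len(length(brk) - 1)) {
      bidx <- sig[(brk[j] + 1):brk[j + 1]]
      b0 <- min(bidx); b1 <- max(bidx)
      top <- bidx[which.max(s[bidx])]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = (b0 - 1) * bs, end = b1 * bs,
        summit = (top - 0.5) * bs,
        score = -log10(max(min(p[bidx]), .Machine$double.xmin)),
        fold_enrichment = max(fold[bidx]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    peaks <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                        summit = numeric(), score = numeric(),
                        fold_enrichment = numeric(), stringsAsFactors = FALSE)
  } else {
    peaks <- do.call(rbind, out)
  }
  peaks$timepoint <- rep(timepoint, nrow(peaks))
  peaks$name <- if (nrow(peaks)) sprintf("peak%04d", seq_len(nrow(peaks))) else character()
  peaks
}

#' Signal of peak sets across timepoints
#'
#' Quantifies each peak set's mean normalized signal over peak centers
#' `+- flank` in every timepoint's track: row s, column t is the mean over
#' set s's windows of track t. Applied to peaks called in one timepoint and
#' evaluated in all others, this is the transience readout: signal at a
#' stalling hotspot is highest in its own timepoint and decays by the next.
#'
#' @param peak_sets a single peak data frame or a named list of them.
#' @param tracks named list of normalized [coverage_track()]s, one per
#'   timepoint (order = column order).
#' @param flank half-window around each peak center in bp (default 1000).
#' @return numeric matrix `[peak set x timepoint]`.
#' @export
peak_transience <- function(peak_sets, tracks, flank = 1000) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peaks = peak_sets)
  mat <- matrix(NA_real_, nrow = length(peak_sets), ncol = length(tracks),
                dimnames = list(names(peak_sets), names(tracks)))
  for (s in seq_along(peak_sets)) {
    pk <- peak_sets[[s]]
    if (nrow(pk) == 0) next
    centers <- if ("summit" %in% names(pk) && !anyNA(pk$summit)) pk$summit
               else interval_centers(pk)
    for (t in seq_along(tracks)) {
      tr <- tracks[[t]]
      vals <- quantify_at_intervals(
        tr, data.frame(chrom = pk$chrom,
                       start = pmax(0, centers - flank),
                       end = centers + flank))
      mat[s, t] <- mean(vals, na.rm = TRUE)
    }
  }
  mat
}

#' Replicate concordance of peak signal
#'
#' Mean signal per peak in each of two replicate tracks plus their Spearman
#' rank correlation. With fewer than two peaks the correlation is undefined
#' and returned as NA with a warning.
#'
#' @param peaks a peak data frame.
#' @param track_a,track_b replicate [coverage_track()]s (normalized).
#' @return list with `signal` (data frame: name, rep_a, rep_b) and `rho`.
#' @export
replicate_concordance <- function(peaks, track_a, track_b) {
  a <- quantify_at_intervals(track_a, peaks)
  b <- quantify_at_intervals(track_b, peaks)
  rho <- if (nrow(peaks) < 2) {
    warning("fewer than 2 peaks: rank correlation undefined")
    NA_real_
  } else {
    stats::cor(a, b, method = "spearman", use = "complete.obs")
  }
  list(signal = data.frame(name = peaks$name %||% seq_len(nrow(peaks)),
                           rep_a = a, rep_b = b),
       rho = rho)
}

#' Base and hexamer composition of sequences
#'
#' AT percentage over A+C+G+T (ambiguous bases excluded) and sliding 6-mer
#' counts (case-insensitive; windows containing non-ACGT characters are
#' skipped).
#'
#' @param sequences character vector or `Biostrings::DNAStringSet`.
#' @return list with `at_percent` (scalar, 0-100) and `hexamers` (named
#'   integer vector of observed 6-mer counts, decreasing).
#' @export
sequence_composition <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  base <- colSums(Biostrings::letterFrequency(sequences, c("A", "C", "G", "T")))
  tot <- sum(base)
  at <- if (tot > 0) 100 * (base[["A"]] + base[["T"]]) / tot else NA_real_
  long_enough <- sequences[Biostrings::width(sequences) >= 6]
  hex <- if (length(long_enough)) {
    counts <- colSums(Biostrings::oligonucleotideFrequency(long_enough, width = 6,
                                                           step = 1))
    counts <- counts[counts > 0]
    sort(counts, decreasing = TRUE)
  } else {
    stats::setNames(integer(), character())
  }
  list(at_percent = as.numeric(at), hexamers = hex)
}
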