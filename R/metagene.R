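#' Anchor-centered metagene profile
#'
#' Averages track signal over windows of `+- flank` bp around the center of
#' each anchor interval, resampled to `n_bins` positions. Minus-strand
#' anchors are reversed when `strand_aware`, so position is read in the
#' anchor's own orientation. Windows exceeding the chromosome contribute
#' only their covered bins; the mean at each position is over contributing
#' anchors (NaN where none contribute).
#'
#' @param track a [coverage_track()].
#' @param anchors a [gintervals()]-style data frame.
#' @param flank half-window in bp.
#' @param n_bins output resolution (default one point per track bin).
#' @param strand_aware reverse minus-strand anchors (default FALSE).
#' @return list of class `metagene_profile`: `position` (bp relative to
#'   anchor center), `mean`, `n` (anchors contributing per position),
#'   `n_anchors`.
#' @export
profile_at_anchors <- function(track, anchors, flank, n_bins = NULL,
                               strand_aware = FALSE) {
  stopifnot(flank > 0, nrow(anchors) > 0)
  if (is.null(n_bins)) n_bins <- max(2L, round(2 * flank / track$bin_size))
  rel <- -flank + (seq_len(n_bins) - 0.5) * (2 * flank / n_bins)
  centers <- interval_centers(anchors)
  mat <- matrix(NA_real_, nrow = nrow(anchors), ncol = n_bins)
  for (i in seq_len(nrow(anchors))) {
    r <- if (strand_aware && !is.null(anchors$strand) &&
             anchors$strand[i] == "-") -rel else rel
    mat[i, ] <- track_values_at(track, rep(anchors$chrom[i], n_bins),
                                centers[i] + r)
  }
  n <- colSums(!is.na(mat))
  structure(list(position = rel,
                 mean = colMeans(mat, na.rm = TRUE),
                 n = n, n_anchors = nrow(anchors)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %d positions over %d anchors, mean %.4g\n",
              length(x$position), x$n_anchors, mean(x$mean, na.rm = TRUE)))
  invisible(x)
}

#' Gene-body-scaled metagene profile
#'
#' Resamples each gene body to `n_bins` positions from TSS to TTS in the
#' gene's transcription orientation and averages across genes, so profiles
#' are comparable across gene lengths.
#'
#' @param track a [coverage_track()].
#' @param genes gene table with strand.
#' @param n_bins output resolution (default 100).
#' @return list of class `metagene_profile` with `position` the scaled
#'   coordinate in (0, 1).
#' @export
scaled_gene_profile <- function(track, genes, n_bins = 100) {
  stopifnot(nrow(genes) > 0, n_bins >= 2)
  frac <- (seq_len(n_bins) - 0.5) / n_bins
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins)
  for (i in seq_len(nrow(genes))) {
    f <- if (genes$strand[i] == "-") rev(frac) else frac
    pos <- genes$start[i] + f * (genes$end[i] - genes$start[i])
    mat[i, ] <- track_values_at(track, rep(genes$chrom[i], n_bins), pos)
  }
  structure(list(position = frac, mean = colMeans(mat, na.rm = TRUE),
                 n = colSums(!is.na(mat)), n_anchors = nrow(genes)),
            class = "metagene_profile")
}

#' Mean signal per interval
#'
#' Length-weighted mean of the track bins covered by each interval (partial
#' bins weighted by their covered length). Intervals outside the track give
#' NA.
#'
#' @param track a [coverage_track()].
#' @param intervals a [gintervals()]-style data frame.
#' @return numeric vector, one mean per interval.
#' @export
quantify_at_intervals <- function(track, intervals) {
  bs <- track$bin_size
  n <- nrow(intervals)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- track$bins[[intervals$chrom[i]]]
    if (is.null(v)) next
    s <- max(0, intervals$start[i])
    e <- min(length(v) * bs, intervals$end[i])
    if (e <= s) next
    b0 <- floor(s / bs); b1 <- ceiling(e / bs) - 1
    idx <- b0:b1
    lo <- pmax(idx * bs, s)
    hi <- pmin((idx + 1) * bs, e)
    w <- hi - lo
    out[i] <- sum(v[idx + 1] * w) / sum(w)
  }
  out
}

#' Ratio of two tracks quantified per interval
#'
#' Companion to [quantify_at_intervals()] for normalised readouts (e.g., a
#' damage mark over its unmodified histone): per-interval mean of the
#' numerator track divided by that of the denominator track; zero or missing
#' denominators give NaN.
#'
#' @param numerator,denominator [coverage_track()]s.
#' @param intervals a [gintervals()]-style data frame.
#' @return numeric vector of ratios.
#' @export
quantify_ratio <- function(numerator, denominator, intervals) {
  a <- quantify_at_intervals(numerator, intervals)
  b <- quantify_at_intervals(denominator, intervals)
  ifelse(is.na(b) | b == 0, NaN, a / b)
}

#' Density-decline estimate over long genes
#'
#' The replication-speed proxy: a TSS-anchored, strand-aware metagene of the
#' track over genes longer than `min_length` is compared between an upstream
#' baseline window `[-baseline_window, 0)` and its minimum over
#' `(0, scan_window]` after moving-average smoothing (`smooth_bw` bp), giving
#' `percent_reduction = 100 * (baseline - minimum) / baseline` and the
#' minimum's position downstream of the TSS.
#'
#' @param track a [coverage_track()].
#' @param genes gene table; only genes with length `> min_length` are used.
#' @param min_length gene length cutoff in bp (default 100 kb).
#' @param scan_window bp downstream of the TSS scanned for the minimum
#'   (default 100 kb).
#' @param baseline_window bp upstream of the TSS averaged as baseline
#'   (default 10 kb).
#' @param smooth_bw moving-average bandwidth in bp (default 5 kb).
#' @return list of class `density_decline_estimate`: `baseline`, `minimum`,
#'   `min_position` (bp downstream of TSS), `percent_reduction`, `n_genes`,
#'   `profile` (position, mean, smoothed).
#' @export
density_decline <- function(track, genes, min_length = 100e3,
                            scan_window = 100e3, baseline_window = 10e3,
                            smooth_bw = 5e3) {
  g <- genes[(genes$end - genes$start) > min_length, , drop = FALSE]
  if (nrow(g) == 0) stop("no genes longer than min_length")
  bs <- track$bin_size
  rel <- seq(-baseline_window + bs / 2, scan_window - bs / 2, by = bs)
  tss <- ifelse(g$strand == "+", g$start, g$end)
  mat <- matrix(NA_real_, nrow = nrow(g), ncol = length(rel))
  for (i in seq_len(nrow(g))) {
    r <- if (g$strand[i] == "-") -rel else rel
    mat[i, ] <- track_values_at(track, rep(g$chrom[i], length(rel)),
                                tss[i] + r)
  }
  prof <- colMeans(mat, na.rm = TRUE)
  up <- rel < 0
  baseline <- mean(prof[up], na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline signal is not positive")
  k <- max(1L, round(smooth_bw / bs))
  body <- prof[!up]
  smoothed <- moving_average(body, k)
  imin <- which.min(smoothed)
  minimum <- smoothed[imin]
  structure(list(baseline = baseline, minimum = minimum,
                 min_position = rel[!up][imin] + bs / 2,
                 percent_reduction = 100 * (baseline - minimum) / baseline,
                 n_genes = nrow(g),
                 profile = data.frame(position = rel, mean = prof,
                                      smoothed = c(rep(NA_real_, sum(up)),
                                                   smoothed))),
            class = "density_decline_estimate")
}

#' @export
print.density_decline_estimate <- function(x, ...) {
  cat(sprintf(paste0("density decline over %d genes: %.1f%% reduction, ",
                     "minimum %.0f kb downstream of TSS\n"),
              x$n_genes, x$percent_reduction, x$min_position / 1000))
  invisible(x)
}

#' Windowed correlation of two tracks
#'
#' Sums both tracks into non-overlapping windows, keeps windows where both
#' sums reach `min_reads`, and reports the Pearson correlation of the
#' retained pairs.
#'
#' @param track_a,track_b [coverage_track()]s with matching bins.
#' @param window window size in bp (default 1000).
#' @param min_reads minimum read sum in both windows (default 10).
#' @return list: `r` (Pearson correlation), `n_windows` (retained),
#'   `n_total`.
#' @export
windowed_correlation <- function(track_a, track_b, window = 1000,
                                 min_reads = 10) {
  check_compatible(track_a, track_b)
  bs <- track_a$bin_size
  per <- max(1L, round(window / bs))
  rebin <- function(v) {
    nw <- floor(length(v) / per)
    if (nw == 0) return(numeric())
    colSums(matrix(v[seq_len(nw * per)], nrow = per))
  }
  a <- unlist(lapply(track_a$bins, rebin), use.names = FALSE)
  b <- unlist(lapply(track_b$bins, rebin), use.names = FALSE)
  keep <- a >= min_reads & b >= min_reads
  n <- sum(keep)
  r <- if (n >= 3 && stats::sd(a[keep]) > 0 && stats::sd(b[keep]) > 0) {
    stats::cor(a[keep], b[keep])
  } else NA_real_
  list(r = r, n_windows = n, n_total = length(a))
}
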