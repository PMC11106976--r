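#' Binned coverage tracks
#'
#' A coverage track stores one nonnegative numeric vector of fixed-width bins
#' per chromosome. Bin `i` covers bp `[(i-1)*bin_size, i*bin_size)`. This is
#' the carrier for BrdU-Seq, ChIP-Seq and Chr-RNA-Seq signal throughout the
#' package.
#'
#' @param bins named list of numeric vectors (one per chromosome).
#' @param bin_size bin width in bp.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(bins, bin_size) {
  stopifnot(is.list(bins), !is.null(names(bins)) || length(bins) == 0,
            bin_size >= 1)
  for (ch in names(bins)) {
    b <- bins[[ch]]
    if (any(b < 0, na.rm = TRUE)) stop("negative bin value on ", ch)
    bins[[ch]] <- as.numeric(b)
  }
  structure(list(bins = bins, bin_size = as.numeric(bin_size)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosome(s), bin_size=%d bp, mass=%.4g\n",
              length(x$bins), as.integer(x$bin_size), library_size(x)))
  invisible(x)
}

#' Total signal mass of a track
#'
#' Sum of all bin values; used for depth scaling between libraries.
#' @param track a [coverage_track()].
#' @export
library_size <- function(track) {
  sum(vapply(track$bins, sum, numeric(1)))
}

track_chroms <- function(track) names(track$bins)

# values of the bins containing the given positions; NA outside the track
track_values_at <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    v <- track$bins[[ch]]
    if (is.null(v)) next
    sel <- which(chrom == ch)
    idx <- floor(pos[sel] / track$bin_size) + 1
    ok <- idx >= 1 & idx <= length(v) & pos[sel] >= 0
    out[sel[ok]] <- v[idx[ok]]
  }
  out
}

check_compatible <- function(a, b) {
  if (a$bin_size != b$bin_size)
    stop("tracks have mismatched bin_size (", a$bin_size, " vs ", b$bin_size, ")")
  if (!setequal(track_chroms(a), track_chroms(b)))
    stop("tracks have mismatched chromosome sets")
  for (ch in track_chroms(a)) {
    if (length(a$bins[[ch]]) != length(b$bins[[ch]]))
      stop("tracks have different lengths on ", ch)
  }
  invisible(TRUE)
}

#' Read a bedGraph into a binned coverage track
#'
#' Records must be sorted and non-overlapping within each chromosome. Spans
#' not aligned to the bin grid are re-binned by length-weighted mean, which
#' conserves total signal mass (`sum(value * span)`). Uncovered bins are 0.
#'
#' @param path bedGraph file (4 tab-separated columns, no header).
#' @param bin_size bin width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   defaults to the last covered coordinate per chromosome.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "numeric", "numeric", "numeric"),
                      col.names = c("chrom", "start", "end", "value")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(df) || nrow(df) == 0) {
    bins <- list()
    if (!is.null(chrom_lengths)) {
      bins <- lapply(chrom_lengths, function(L) numeric(ceiling(L / bin_size)))
      names(bins) <- names(chrom_lengths)
    }
    return(coverage_track(bins, bin_size))
  }
  if (any(df$value < 0)) stop("negative bedGraph value")
  if (any(df$start >= df$end)) stop("invalid bedGraph span (start >= end)")
  bins <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping bedGraph records on ", ch)
    L <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(d$end)
    n <- ceiling(L / bin_size)
    acc <- numeric(n)
    # distribute value * covered-length into every bin the span touches
    for (i in seq_len(nrow(d))) {
      b0 <- floor(d$start[i] / bin_size)
      b1 <- ceiling(d$end[i] / bin_size) - 1
      idx <- b0:b1
      lo <- pmax(idx * bin_size, d$start[i])
      hi <- pmin((idx + 1) * bin_size, d$end[i])
      acc[idx + 1] <- acc[idx + 1] + d$value[i] * (hi - lo)
    }
    bins[[ch]] <- acc / bin_size
  }
  if (!is.null(chrom_lengths)) {
    for (ch in setdiff(names(chrom_lengths), names(bins)))
      bins[[ch]] <- numeric(ceiling(chrom_lengths[[ch]] / bin_size))
  }
  coverage_track(bins, bin_size)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are merged into single records; zero-valued
#' runs are omitted. Output is byte-reproducible for identical input.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  for (ch in track_chroms(track)) {
    v <- track$bins[[ch]]
    if (length(v) == 0) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(ch,
                     fmt_num(starts[keep] * track$bin_size),
                     fmt_num(ends[keep] * track$bin_size),
                     fmt_num(r$values[keep]), sep = "\t"), con)
  }
  invisible(path)
}
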