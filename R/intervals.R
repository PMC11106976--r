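#' Genomic intervals
#'
#' The package represents genomic intervals as plain data frames in BED-style
#' 0-based half-open coordinates: `start` is the first base of the interval,
#' `end` is one past the last. This single internal convention is applied to
#' every coordinate the package touches; 1-based inputs (structural-variant
#' tables) are converted on read.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, `start < end`.
#' @param strand strand per interval, one of `"+"`, `"-"`, `"."`.
#' @param name optional label per interval.
#' @param score optional numeric score per interval.
#' @return A `data.frame` of class `genomic_intervals` with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @examples
#' gintervals("chr1", 100, 200)
#' @export
gintervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                       score = NA_real_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: start=%s end=%s (need 0 <= start < end)",
                 what, bad[1], format(df$start[bad[1]]), format(df$end[bad[1]])))
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' Read a BED file
#'
#' Reads BED3 to BED6 (tab-separated, no header). Coordinates are kept as the
#' file's 0-based half-open values.
#'
#' @param path file path.
#' @return A [gintervals()] data frame, rows in input order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(gintervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 which(ncol < 3)[1]))
  }
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(get_col(2L, NA)))
  end <- suppressWarnings(as.numeric(get_col(3L, NA)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinate",
                 which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("invalid interval at line %d: start >= end", bad[1]))
  }
  gintervals(
    chrom = get_col(1L, NA_character_),
    start = start,
    end = end,
    name = get_col(4L, NA_character_),
    score = suppressWarnings(as.numeric(get_col(5L, NA_character_))),
    strand = ifelse(get_col(6L, ".") %in% c("+", "-"), get_col(6L, "."), ".")
  )
}

#' Write intervals as BED
#'
#' Writes BED3 when no name/score/strand is set, BED6 otherwise. A canonical
#' 6-column BED round-trips byte-identically through [read_bed()].
#'
#' @param intervals a [gintervals()] data frame.
#' @param path output path.
#' @param extra_cols optional character vector of further columns to append
#'   (BED6+).
#' @export
write_bed <- function(intervals, path, extra_cols = NULL) {
  validate_intervals(intervals)
  has6 <- nrow(intervals) > 0 &&
    (any(!is.na(intervals$name)) || any(!is.na(intervals$score)) ||
       any(intervals$strand != ".") || length(extra_cols) > 0)
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (nrow(intervals) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (has6) {
    cols <- cbind(
      intervals$chrom, fmt_num(intervals$start), fmt_num(intervals$end),
      ifelse(is.na(intervals$name), ".", intervals$name),
      ifelse(is.na(intervals$score), "0", fmt_num(intervals$score)),
      intervals$strand
    )
    for (ec in extra_cols) cols <- cbind(cols, fmt_num(intervals[[ec]]))
  } else {
    cols <- cbind(intervals$chrom, fmt_num(intervals$start), fmt_num(intervals$end))
  }
  writeLines(apply(cols, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

# convert 0-based half-open intervals to GRanges (1-based closed)
gi_to_granges <- function(df) {
  strand <- if (!is.null(df$strand)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else rep("*", nrow(df))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand
  )
}

#' Interval centers
#'
#' Midpoint (floor) of each interval, in bp.
#' @param intervals a [gintervals()] data frame.
#' @return numeric vector of center positions.
#' @export
interval_centers <- function(intervals) {
  floor((intervals$start + intervals$end) / 2)
}
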