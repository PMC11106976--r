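#' Read a structural-rearrangement table
#'
#' Parses a COSMIC-style TSV with one rearrangement per row and two breakpoint
#' windows per record. Expected header columns: `id`, `chrom1`, `pos1_start`,
#' `pos1_end`, `chrom2`, `pos2_start`, `pos2_end`, `sv_class`. Positions are
#' 1-based inclusive in the file and converted to the package's 0-based
#' half-open convention on read. For intrachromosomal records the
#' lower-coordinate breakpoint becomes `left`; interchromosomal records keep
#' chrom1 as left by convention.
#'
#' @param path TSV path.
#' @return A `data.frame` of class `rearrangements` with columns `id`,
#'   `chrom_l`, `start_l`, `end_l`, `chrom_r`, `start_r`, `end_r`, `sv_class`.
#' @export
read_sv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("id", "chrom1", "pos1_start", "pos1_end",
            "chrom2", "pos2_start", "pos2_end", "sv_class")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("SV table schema error: missing column(s) ", paste(missing, collapse = ", "))
  # 1-based inclusive -> 0-based half-open
  s1 <- df$pos1_start - 1; e1 <- df$pos1_end
  s2 <- df$pos2_start - 1; e2 <- df$pos2_end
  swap <- df$chrom1 == df$chrom2 & s1 > s2
  out <- data.frame(
    id = as.character(df$id),
    chrom_l = ifelse(swap, df$chrom2, df$chrom1),
    start_l = ifelse(swap, s2, s1),
    end_l = ifelse(swap, e2, e1),
    chrom_r = ifelse(swap, df$chrom1, df$chrom2),
    start_r = ifelse(swap, s1, s2),
    end_r = ifelse(swap, e1, e2),
    sv_class = as.character(df$sv_class),
    stringsAsFactors = FALSE
  )
  if (any(out$start_l >= out$end_l | out$start_r >= out$end_r))
    stop("invalid breakpoint window (start >= end) in SV table")
  class(out) <- c("rearrangements", "data.frame")
  out
}

#' Expand rearrangements into breakpoint windows
#'
#' Both breakpoints of each rearrangement are treated as independent events:
#' every record yields two intervals, each optionally expanded by `flank` bp
#' on both sides (clipped at 0). Names carry the record id and side (L/R).
#'
#' @param rearrangements a [read_sv_table()] data frame.
#' @param flank bp added on each side of each breakpoint window (default 0).
#' @return a [gintervals()] data frame with `2 * nrow(rearrangements)` rows.
#' @export
breakpoint_windows <- function(rearrangements, flank = 0) {
  r <- rearrangements
  gintervals(
    chrom = c(rbind(r$chrom_l, r$chrom_r)),
    start = pmax(0, c(rbind(r$start_l, r$start_r)) - flank),
    end = c(rbind(r$end_l, r$end_r)) + flank,
    name = c(rbind(paste0(r$id, "_L"), paste0(r$id, "_R")))
  )
}

#' Write a structural-rearrangement table
#'
#' Inverse of [read_sv_table()]: coordinates are converted back to 1-based
#' inclusive positions.
#' @param rearrangements a `rearrangements` data frame.
#' @param path output TSV path.
#' @export
write_sv_table <- function(rearrangements, path) {
  r <- rearrangements
  out <- data.frame(
    id = r$id,
    chrom1 = r$chrom_l, pos1_start = r$start_l + 1, pos1_end = r$end_l,
    chrom2 = r$chrom_r, pos2_start = r$start_r + 1, pos2_end = r$end_r,
    sv_class = r$sv_class
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
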