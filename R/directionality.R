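#' Classify peaks by transcription-replication directionality
#'
#' Each peak is assigned by its center (summit when available) to the
#' transcribed gene containing it; membership by center gives a single,
#' deterministic assignment. A peak whose center lies in no transcribed gene
#' is `not_transcribed`. Within a transcribed gene the class follows the
#' gene's replication-fork direction: forks entering from both ends give
#' `undetermined`; otherwise the peak is `codirectional` when the fork moves
#' with transcription (gene `+` and rightward fork, or gene `-` and leftward
#' fork) and `head_on` when against it. When the center falls inside two
#' overlapping transcribed genes, the gene with the higher transcription
#' level wins (the dominant transcription unit defines the collision
#' context); the event is reported via a message.
#'
#' @param peaks a peak data frame ([call_peaks()] output or any
#'   [gintervals()]); the `summit` column is used as center when present.
#' @param genes gene table with columns chrom, start, end, strand, name,
#'   transcription_level.
#' @param fork_directions named character vector, gene name ->
#'   `rightward`/`leftward`/`both`; must cover all transcribed genes.
#' @param membership `"center"` (default) or `"overlap"` (any overlap between
#'   the peak interval and a transcribed gene, ties broken as above).
#' @return data frame with columns `class` (factor with levels codirectional,
#'   head_on, undetermined, not_transcribed) and `gene` (assigned gene name
#'   or NA), one row per peak in input order.
#' @export
classify_peaks <- function(peaks, genes, fork_directions,
                           membership = c("center", "overlap")) {
  membership <- match.arg(membership)
  lev <- c("codirectional", "head_on", "undetermined", "not_transcribed")
  n <- nrow(peaks)
  if (n == 0) {
    return(data.frame(class = factor(character(), levels = lev),
                      gene = character(), stringsAsFactors = FALSE))
  }
  tg <- genes[genes$transcription_level > 0, , drop = FALSE]
  missing_dir <- setdiff(tg$name, names(fork_directions))
  if (length(missing_dir))
    stop("fork_directions missing for transcribed gene(s): ",
         paste(utils::head(missing_dir, 3), collapse = ", "))
  assigned_gene <- rep(NA_character_, n)
  if (nrow(tg) > 0) {
    if (membership == "center") {
      centers <- if ("summit" %in% names(peaks) && !anyNA(peaks$summit))
        peaks$summit else interval_centers(peaks)
      q <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(centers + 1, centers + 1))
    } else {
      q <- gi_to_granges(peaks)
    }
    subj <- gi_to_granges(tg)
    hits <- GenomicRanges::findOverlaps(q, subj, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (anyDuplicated(qh)) {
      message(sum(duplicated(qh)),
              " peak(s) inside overlapping transcribed genes; ",
              "assigned to the higher-expressed gene")
    }
    # tie-break: highest transcription level
    ord <- order(qh, -tg$transcription_level[sh])
    keep <- !duplicated(qh[ord])
    assigned_gene[qh[ord][keep]] <- tg$name[sh[ord][keep]]
  }
  cls <- rep("not_transcribed", n)
  has <- !is.na(assigned_gene)
  if (any(has)) {
    g <- match(assigned_gene[has], genes$name)
    dir <- unname(fork_directions[assigned_gene[has]])
    strand <- genes$strand[g]
    cls[has] <- ifelse(dir == "both", "undetermined",
                       ifelse((strand == "+" & dir == "rightward") |
                                (strand == "-" & dir == "leftward"),
                              "codirectional", "head_on"))
  }
  data.frame(class = factor(cls, levels = lev), gene = assigned_gene,
             stringsAsFactors = FALSE)
}

#' Tabulate directionality categories
#'
#' Counts per class plus percentages of the in-gene classes (codirectional,
#' head-on, undetermined) over the total number of in-gene peaks, and of all
#' classes over all peaks; percentages are reported to two decimals.
#'
#' @param classes a factor/character vector of classes, the data frame from
#'   [classify_peaks()], or a named count vector (names = classes).
#' @return list of class `category_table` with `counts`, `total`,
#'   `total_in_gene`, `percent_in_gene`, `percent_all`.
#' @export
category_percentages <- function(classes) {
  lev <- c("codirectional", "head_on", "undetermined", "not_transcribed")
  if (is.data.frame(classes)) classes <- classes$class
  if (is.numeric(classes)) {
    counts <- stats::setNames(rep(0, length(lev)), lev)
    counts[names(classes)] <- classes
  } else {
    counts <- table(factor(as.character(classes), levels = lev))
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  in_gene <- counts[c("codirectional", "head_on", "undetermined")]
  total_in_gene <- sum(in_gene)
  total <- sum(counts)
  pct_in <- if (total_in_gene > 0) round(100 * in_gene / total_in_gene, 2) else
    in_gene * NA_real_
  pct_all <- if (total > 0) round(100 * counts / total, 2) else counts * NA_real_
  structure(list(counts = counts, total = total,
                 total_in_gene = total_in_gene,
                 percent_in_gene = pct_in, percent_all = pct_all),
            class = "category_table")
}

#' @export
print.category_table <- function(x, ...) {
  cat("Directionality categories\n")
  for (k in names(x$counts)) {
    cat(sprintf("  %-16s %6d", k, as.integer(x$counts[k])))
    if (k %in% names(x$percent_in_gene) && x$total_in_gene > 0)
      cat(sprintf("  (%.2f%% of in-gene)", x$percent_in_gene[k]))
    cat("\n")
  }
  cat(sprintf("  in-gene total: %d of %d peaks\n",
              as.integer(x$total_in_gene), as.integer(x$total)))
  invisible(x)
}
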