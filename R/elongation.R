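#' Time at which a recovery timecourse reaches the control plateau
#'
#' The first time the pre-mRNA level reaches `(1 - tolerance) * plateau`:
#' transcription has re-reached that primer position. By default the
#' crossing is linearly interpolated between the bracketing sample times;
#' `interpolate = FALSE` snaps to the first sample at or above threshold
#' (the coarser sampled-grid procedure).
#'
#' @param levels numeric vector of normalized pre-mRNA levels.
#' @param times sample times in minutes (same length, increasing).
#' @param plateau control plateau level.
#' @param tolerance fraction of the plateau regarded as recovered
#'   (default 0.1, i.e. threshold at 90% of plateau).
#' @param interpolate linear interpolation of the crossing (default TRUE).
#' @return crossing time in minutes, or NA (flagged via attribute
#'   `reason = "no_crossing"`) when the level never reaches threshold.
#' @export
recovery_time <- function(levels, times, plateau, tolerance = 0.1,
                          interpolate = TRUE) {
  stopifnot(length(levels) == length(times), length(levels) >= 1,
            !is.unsorted(times, strictly = TRUE), plateau > 0)
  thr <- (1 - tolerance) * plateau
  hit <- which(levels >= thr)
  if (length(hit) == 0) {
    return(structure(NA_real_, reason = "no_crossing"))
  }
  i <- hit[1]
  if (i == 1 || !interpolate) return(times[i])
  # linear interpolation across the bracketing samples
  t0 <- times[i - 1]; t1 <- times[i]
  l0 <- levels[i - 1]; l1 <- levels[i]
  if (l1 == l0) return(times[i])
  t0 + (thr - l0) / (l1 - l0) * (t1 - t0)
}

#' Per-segment elongation rates from recovery times
#'
#' Rate over each inter-primer segment: distance between consecutive primer
#' positions divided by the difference of their recovery times. Segments
#' with missing, non-increasing or tied times are undefined (NA) and skipped
#' in the mean gene rate.
#'
#' @param positions_kb primer positions in kb from the TSS (increasing).
#' @param times recovery times in minutes (same length).
#' @return list: `rates` (kb/min per segment, named "pos1-pos2"),
#'   `mean_rate`, `n_segments` (defined ones).
#' @export
segment_rates <- function(positions_kb, times) {
  stopifnot(length(positions_kb) == length(times),
            !is.unsorted(positions_kb, strictly = TRUE))
  dp <- diff(positions_kb)
  dt <- diff(times)
  rates <- ifelse(is.na(dt) | dt <= 0, NA_real_, dp / dt)
  names(rates) <- paste0(utils::head(positions_kb, -1), "-",
                         utils::tail(positions_kb, -1), "kb")
  list(rates = rates,
       mean_rate = if (all(is.na(rates))) NA_real_ else mean(rates, na.rm = TRUE),
       n_segments = sum(!is.na(rates)))
}

#' Percent reduction of an elongation rate versus control
#'
#' `100 * (control - treated) / control`.
#' @param treated_rate,control_rate rates in kb/min.
#' @return percent reduction (negative when treated is faster).
#' @export
percent_rate_reduction <- function(treated_rate, control_rate) {
  stopifnot(control_rate > 0)
  100 * (control_rate - treated_rate) / control_rate
}

#' Estimate elongation rates from a recovery timecourse table
#'
#' End-to-end estimator over a tidy timecourse (columns condition,
#' primer_kb, time_min, level, as produced by [simulate_timecourse()] or
#' read from a TSV): per condition and primer the recovery time against the
#' control condition's plateau (its level at the last sample), then segment
#' rates, mean gene rate, and percent reduction versus the control.
#'
#' @param timecourse data frame with columns `condition`, `primer_kb`,
#'   `time_min`, `level`.
#' @param control name of the control condition (default `"DMSO"`).
#' @param tolerance,interpolate passed to [recovery_time()].
#' @return list of class `elongation_estimate`: per-condition list with
#'   `recovery_times`, `rates`, `mean_rate`, `percent_reduction` (NA for the
#'   control itself).
#' @export
estimate_elongation <- function(timecourse, control = "DMSO",
                                tolerance = 0.1, interpolate = TRUE) {
  need <- c("condition", "primer_kb", "time_min", "level")
  stopifnot(all(need %in% names(timecourse)))
  conds <- unique(timecourse$condition)
  if (!control %in% conds)
    stop("control condition '", control, "' not in timecourse")
  primers <- sort(unique(timecourse$primer_kb))
  # plateau per primer from the control's final sample
  plateau <- vapply(primers, function(p) {
    d <- timecourse[timecourse$condition == control &
                      timecourse$primer_kb == p, ]
    d$level[which.max(d$time_min)]
  }, numeric(1))
  res <- lapply(conds, function(cond) {
    rt <- vapply(seq_along(primers), function(k) {
      d <- timecourse[timecourse$condition == cond &
                        timecourse$primer_kb == primers[k], ]
      d <- d[order(d$time_min), ]
      as.numeric(recovery_time(d$level, d$time_min, plateau[k],
                               tolerance = tolerance,
                               interpolate = interpolate))
    }, numeric(1))
    sr <- segment_rates(primers, rt)
    list(recovery_times = stats::setNames(rt, paste0(primers, "kb")),
         rates = sr$rates, mean_rate = sr$mean_rate)
  })
  names(res) <- conds
  ctrl_rate <- res[[control]]$mean_rate
  for (cond in conds) {
    res[[cond]]$percent_reduction <- if (cond == control) NA_real_ else
      percent_rate_reduction(res[[cond]]$mean_rate, ctrl_rate)
  }
  structure(list(conditions = res, control = control, primers_kb = primers),
            class = "elongation_estimate")
}

#' @export
print.elongation_estimate <- function(x, ...) {
  cat("elongation rate estimates (kb/min)\n")
  for (cond in names(x$conditions)) {
    e <- x$conditions[[cond]]
    cat(sprintf("  %-10s mean %.2f", cond, e$mean_rate))
    if (!is.na(e$percent_reduction))
      cat(sprintf("  (%.1f%% vs %s)", e$percent_reduction, x$control))
    cat("\n")
  }
  invisible(x)
}
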