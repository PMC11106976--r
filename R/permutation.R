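#' Distance to the nearest feature
#'
#' For each query interval, the distance in bp to the nearest feature on the
#' same chromosome: 0 when the intervals intersect (the "distance of 0 is an
#' overlap" convention), otherwise the gap between nearest edges, with
#' adjacent half-open intervals reported as 1 so that 0 unambiguously means
#' intersection. Queries on chromosomes with no features get `Inf` and are
#' excluded from downstream overlap fractions.
#'
#' @param queries,features [gintervals()] data frames; `features` must be
#'   non-empty.
#' @return numeric vector, one nonnegative distance (or Inf) per query.
#' @export
closest_distance <- function(queries, features) {
  if (nrow(features) == 0) stop("empty feature set")
  n <- nrow(queries)
  if (n == 0) return(numeric())
  q <- gi_to_granges(queries)
  s <- gi_to_granges(features)
  d <- rep(Inf, n)
  hits <- GenomicRanges::distanceToNearest(q, s, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  gap <- S4Vectors::mcols(hits)$distance
  d[qh] <- ifelse(gap == 0, 0, gap)
  # distanceToNearest reports 0 for both touching and intersecting ranges;
  # only true intersections count as overlap, touching ranges get distance 1
  ov <- GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0
  d[!ov & is.finite(d) & d == 0] <- 1
  d
}

#' Overlap fraction of a distance vector
#'
#' Mean of the indicator `distance == 0` over finite entries.
#' @param distances numeric vector from [closest_distance()].
#' @return scalar in `[0, 1]`.
#' @export
overlap_fraction <- function(distances) {
  d <- distances[is.finite(distances)]
  if (length(d) == 0) return(NA_real_)
  mean(d == 0)
}

#' Permutation test on the difference of overlap fractions
#'
#' Tests H0: the two query sets overlap the feature set equally often, via
#' the statistic `t* = d_bar_A - d_bar_B` where `d_bar_X` is the mean of the
#' Boolean vector `[d_X == 0]`. The null distribution resamples group labels
#' over the pooled Boolean vector: without replacement (`"permutation"`,
#' default — for indicator data the group-A overlap count under label
#' permutation is exactly hypergeometric, which is sampled directly) or with
#' replacement (`"bootstrap"`). The empirical p-value is
#' `(1 + #extreme) / (B + 1)`.
#'
#' @param distances_a,distances_b distance vectors ([closest_distance()]);
#'   infinite entries (feature-free chromosomes) are dropped.
#' @param B number of resamples (default 10000).
#' @param seed optional RNG seed.
#' @param sidedness `"two.sided"` (default), `"greater"` (d_bar_A > d_bar_B)
#'   or `"less"`.
#' @param method `"permutation"` or `"bootstrap"`.
#' @return list of class `permutation_test_result`: `t_star`, `d_bar_a`,
#'   `d_bar_b`, `p_value`, `B`, `sidedness`, `method`, `null_mean`,
#'   `null_sd`, `n_a`, `n_b`.
#' @export
permutation_test <- function(distances_a, distances_b, B = 10000, seed = NULL,
                             sidedness = c("two.sided", "greater", "less"),
                             method = c("permutation", "bootstrap")) {
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  if (anyNA(distances_a) || anyNA(distances_b))
    stop("non-finite (NA) distances")
  a <- distances_a[is.finite(distances_a)] == 0
  b <- distances_b[is.finite(distances_b)] == 0
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("empty distance vector after dropping Inf")
  stopifnot(B >= 1)
  d_bar_a <- mean(a); d_bar_b <- mean(b)
  t_obs <- d_bar_a - d_bar_b
  K <- sum(a) + sum(b)
  t_null <- with_seed(seed, {
    if (method == "permutation") {
      ka <- stats::rhyper(B, m = K, n = na + nb - K, k = na)
      ka / na - (K - ka) / nb
    } else {
      phat <- K / (na + nb)
      stats::rbinom(B, na, phat) / na - stats::rbinom(B, nb, phat) / nb
    }
  })
  eps <- 1e-12
  extreme <- switch(sidedness,
                    two.sided = abs(t_null) >= abs(t_obs) - eps,
                    greater = t_null >= t_obs - eps,
                    less = t_null <= t_obs + eps)
  structure(list(t_star = t_obs, d_bar_a = d_bar_a, d_bar_b = d_bar_b,
                 p_value = (1 + sum(extreme)) / (B + 1),
                 B = B, sidedness = sidedness, method = method,
                 null_mean = mean(t_null), null_sd = stats::sd(t_null),
                 n_a = na, n_b = nb),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("overlap permutation test (%s, %s)\n", x$method, x$sidedness))
  cat(sprintf("  d_bar_A = %.4f (n=%d), d_bar_B = %.4f (n=%d)\n",
              x$d_bar_a, x$n_a, x$d_bar_b, x$n_b))
  cat(sprintf("  t* = %.4f, p = %.4g (B = %d)\n", x$t_star, x$p_value, x$B))
  invisible(x)
}

#' Benjamini-Yekutieli correction
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence:
#' raw p-values are inflated by the harmonic factor `c(m) = sum(1/i)` before
#' the usual step-up minimisation, so adjusted values are never below the
#' Benjamini-Hochberg ones. Output order matches input order.
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values, capped at 1.
#' @export
by_correction <- function(p_values) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  stats::p.adjust(p_values, method = "BY")
}

# fast overlap indicator against a fixed feature set: precompile merged
# feature boundaries per chromosome, then test queries with findInterval
compile_features <- function(features) {
  out <- list()
  for (ch in unique(features$chrom)) {
    f <- features[features$chrom == ch, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    # merge overlapping/touching features
    s <- f$start; e <- f$end
    keep_s <- s[1]; keep_e <- e[1]
    if (nrow(f) > 1) {
      ms <- numeric(0); me <- numeric(0)
      cs <- s[1]; ce <- e[1]
      for (i in 2:nrow(f)) {
        if (s[i] <= ce) ce <- max(ce, e[i])
        else { ms <- c(ms, cs); me <- c(me, ce); cs <- s[i]; ce <- e[i] }
      }
      ms <- c(ms, cs); me <- c(me, ce)
    } else {
      ms <- s; me <- e
    }
    out[[ch]] <- as.numeric(rbind(ms, me))  # sorted boundary vector
  }
  out
}

overlaps_any <- function(compiled, chrom, start, end) {
  out <- logical(length(start))
  for (ch in unique(chrom)) {
    bd <- compiled[[ch]]
    sel <- which(chrom == ch)
    if (is.null(bd)) next
    i_s <- findInterval(start[sel], bd)
    i_e <- findInterval(end[sel] - 0.5, bd)
    # odd index = position inside a merged feature; differing indices = the
    # query spans a boundary, hence covers some feature
    out[sel] <- (i_s %% 2 == 1) | (i_e %% 2 == 1) | (i_e > i_s)
  }
  out
}

#' Genome-shuffle empirical overlap test
#'
#' Observed statistic: number of query intervals overlapping at least one
#' feature. Each iteration relocates every query uniformly at random
#' (length-preserving, within its own chromosome) and recomputes the count;
#' the one-sided enrichment p-value is `(1 + #{null >= observed}) /
#' (iterations + 1)`.
#'
#' @param queries,features [gintervals()] data frames.
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param iterations number of shuffles (default 10000).
#' @param seed optional RNG seed.
#' @return list of class `shuffle_test_result`: `observed`, `null_mean`,
#'   `null_sd`, `p_value`, `iterations`, `n_queries`.
#' @export
genome_shuffle_test <- function(queries, features, genome, iterations = 10000,
                                seed = NULL) {
  stopifnot(iterations >= 1, !is.null(names(genome)))
  if (nrow(queries) == 0) stop("empty query set")
  widths <- queries$end - queries$start
  if (any(widths > genome[queries$chrom]))
    stop("query interval longer than its chromosome")
  compiled <- compile_features(features)
  observed <- sum(overlaps_any(compiled, queries$chrom, queries$start,
                               queries$end))
  max_start <- genome[queries$chrom] - widths
  null_counts <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      st <- floor(stats::runif(nrow(queries)) * (max_start + 1))
      sum(overlaps_any(compiled, queries$chrom, st, st + widths))
    }, numeric(1))
  })
  structure(list(observed = observed,
                 null_mean = mean(null_counts),
                 null_sd = stats::sd(null_counts),
                 p_value = (1 + sum(null_counts >= observed)) / (iterations + 1),
                 iterations = iterations,
                 n_queries = nrow(queries)),
            class = "shuffle_test_result")
}

#' @export
print.shuffle_test_result <- function(x, ...) {
  cat(sprintf("genome-shuffle overlap test: observed %d of %d queries\n",
              x$observed, x$n_queries))
  cat(sprintf("  null %.2f +- %.2f, empirical p = %.4g (%d iterations)\n",
              x$null_mean, x$null_sd, x$p_value, x$iterations))
  invisible(x)
}

#' Shuffle peaks within their host genes
#'
#' Relocates each peak uniformly at random within the gene that contains its
#' center, preserving peak length; peaks without a host gene are left in
#' place and flagged. A peak as long as its gene cannot move.
#'
#' @param peaks a peak / [gintervals()] data frame.
#' @param genes gene table (chrom, start, end, name).
#' @param seed optional RNG seed.
#' @return the peaks data frame with updated `start`/`end` (and `summit`
#'   shifted accordingly when present) plus a logical column `shuffled`.
#' @export
shuffle_within_genes <- function(peaks, genes, seed = NULL) {
  out <- peaks
  out$shuffled <- FALSE
  if (nrow(peaks) == 0) return(out)
  centers <- interval_centers(peaks)
  q <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(centers + 1, centers + 1))
  s <- gi_to_granges(genes)
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE, select = "first")
  with_seed(seed, {
    for (i in which(!is.na(hits))) {
      g <- hits[i]
      len <- peaks$end[i] - peaks$start[i]
      room <- (genes$end[g] - genes$start[g]) - len
      if (room < 0) next  # peak longer than gene: cannot be contained
      new_start <- genes$start[g] + floor(stats::runif(1) * (room + 1))
      shift <- new_start - out$start[i]
      out$start[i] <- new_start
      out$end[i] <- new_start + len
      if ("summit" %in% names(out) && !is.na(out$summit[i]))
        out$summit[i] <- out$summit[i] + shift
      out$shuffled[i] <- TRUE
    }
  })
  out
}
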