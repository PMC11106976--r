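# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-stage seed derived from a global seed; stays < 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 100000L) * 17477L + (h %% 17477L)
}

# centred moving average; shrinks the window at the edges
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - half), n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
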