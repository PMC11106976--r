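test_that("nearest-feature distances follow the overlap-is-zero convention", {
  feats <- gintervals("chr1", c(150, 250), c(300, 320))
  # intersection -> 0
  expect_equal(closest_distance(gintervals("chr1", 100, 200), feats), 0)
  # gap between nearest edges
  expect_equal(closest_distance(gintervals("chr1", 100, 140),
                                gintervals("chr1", 250, 300)), 110)
  expect_equal(closest_distance(gintervals("chr1", 100, 200),
                                gintervals("chr1", 250, 300)), 50)
  # adjacent half-open intervals do not intersect: reported as 1
  expect_equal(closest_distance(gintervals("chr1", 100, 200),
                                gintervals("chr1", 200, 300)), 1)
  # feature-free chromosome -> Inf sentinel
  d <- closest_distance(gintervals(c("chr1", "chr9"), c(100, 100),
                                   c(200, 200)), feats)
  expect_equal(d[1], 0)
  expect_equal(d[2], Inf)
  expect_error(closest_distance(gintervals("chr1", 1, 2),
                                gintervals(character(), numeric(), numeric())),
               "empty")
})

test_that("distances agree with a brute-force interval arithmetic oracle", {
  set.seed(51)
  brute <- function(qs, qe, fs, fe) {
    d <- numeric(length(qs))
    for (i in seq_along(qs)) {
      overlap <- fs < qe[i] & fe > qs[i]
      if (any(overlap)) { d[i] <- 0; next }
      gap <- pmax(fs - qe[i], qs[i] - fe)
      d[i] <- max(min(gap), 1)
    }
    d
  }
  for (rep in 1:10) {
    nq <- sample(1:20, 1); nf <- sample(1:20, 1)
    qs <- sample(0:5000, nq); fs <- sample(0:5000, nf)
    q <- gintervals("chr1", qs, qs + sample(1:300, nq, replace = TRUE))
    f <- gintervals("chr1", fs, fs + sample(1:300, nf, replace = TRUE))
    expect_equal(closest_distance(q, f),
                 brute(q$start, q$end, f$start, f$end))
  }
})

test_that("overlap fraction averages the zero-distance indicator", {
  expect_equal(overlap_fraction(c(0, 37, 0, 5)), 0.5)
  expect_equal(overlap_fraction(c(0, 0, 0)), 1)
  expect_equal(overlap_fraction(c(3, 9)), 0)
  # infinite sentinels are excluded
  expect_equal(overlap_fraction(c(0, Inf, 5, Inf)), 0.5)
})

test_that("identical groups give t* = 0 and p near 1", {
  d <- c(0, 0, 5, 9, 0, 3)
  r <- permutation_test(d, d, B = 2000, seed = 1)
  expect_equal(r$t_star, 0)
  expect_gt(r$p_value, 0.9)
})

test_that("maximally separated groups reach the smallest attainable p", {
  a <- rep(0, 50)        # all overlap
  b <- rep(100, 50)      # none overlap
  r <- permutation_test(a, b, B = 10000, seed = 2)
  expect_equal(r$t_star, 1)
  expect_equal(r$p_value, 1 / 10001)
})

test_that("Monte-Carlo p matches exhaustive enumeration for small groups", {
  # enumerate all label splits of the pooled Boolean vector
  exhaustive_p <- function(a_bool, b_bool) {
    pool <- c(a_bool, b_bool)
    na <- length(a_bool)
    t_obs <- mean(a_bool) - mean(b_bool)
    splits <- utils::combn(length(pool), na)
    t_null <- apply(splits, 2, function(ix)
      mean(pool[ix]) - mean(pool[-ix]))
    mean(abs(t_null) >= abs(t_obs) - 1e-12)
  }
  cases <- list(
    list(a = c(TRUE, TRUE, FALSE), b = c(FALSE, FALSE, FALSE)),
    list(a = c(TRUE, TRUE, TRUE, FALSE, FALSE), b = c(TRUE, FALSE, FALSE)),
    list(a = rep(TRUE, 6), b = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  )
  for (cs in cases) {
    da <- ifelse(cs$a, 0, 10)
    db <- ifelse(cs$b, 0, 10)
    p_ex <- exhaustive_p(cs$a, cs$b)
    B <- 10000
    p_mc <- permutation_test(da, db, B = B, seed = 3)$p_value
    se <- sqrt(p_ex * (1 - p_ex) / B)
    expect_lt(abs(p_mc - p_ex), 3 * se + 2 / B)
  }
})

test_that("bootstrap resampling mode is available and consistent under H0", {
  d <- c(rep(0, 20), rep(5, 30))
  r <- permutation_test(d, d, B = 2000, seed = 4, method = "bootstrap")
  expect_equal(r$method, "bootstrap")
  expect_gt(r$p_value, 0.5)
})

test_that("non-finite distance inputs are rejected", {
  expect_error(permutation_test(c(0, NA), c(0, 1), B = 10), "NA")
})

test_that("BY adjustment matches the closed-form step-up computation", {
  by_oracle <- function(p) {
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    o <- order(p)
    adj <- numeric(m)
    sorted <- p[o]
    run <- Inf
    for (j in m:1) {
      run <- min(run, m * cm / j * sorted[j])
      adj[j] <- min(1, run)
    }
    out <- numeric(m)
    out[o] <- adj
    out
  }
  # worked example: c(3) = 11/6, all three adjust to 0.055
  expect_equal(by_correction(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  # single p with m = 1, c = 1 stays itself
  expect_equal(by_correction(0.2), 0.2)
  set.seed(52)
  for (rep in 1:10) {
    p <- runif(sample(1:25, 1))
    adj <- by_correction(p)
    expect_equal(adj, by_oracle(p))
    expect_true(all(adj >= p))
    expect_true(all(adj >= stats::p.adjust(p, "BH")))
    expect_true(all(adj <= 1))
  }
})

test_that("genome shuffle: full-coverage features give p = 1", {
  genome <- c(chr1 = 100000)
  q <- gintervals("chr1", c(100, 5000), c(600, 5500))
  feats <- gintervals("chr1", 0, 100000)
  r <- genome_shuffle_test(q, feats, genome, iterations = 50, seed = 5)
  expect_equal(r$observed, 2)
  expect_equal(r$p_value, 1)
})

test_that("genome shuffle: depleted observed overlap gives p > 0.5", {
  set.seed(53)
  genome <- c(chr1 = 1e6)
  # features cover half the chromosome; queries placed in the feature-free half
  feats <- gintervals("chr1", seq(0, 499000, by = 10000),
                      seq(5000, 504000, by = 10000))
  q <- gintervals("chr1", seq(510000, 990000, by = 20000),
                  seq(510400, 990400, by = 20000))
  r <- genome_shuffle_test(q, feats, genome, iterations = 200, seed = 6)
  expect_gt(r$p_value, 0.5)
})

test_that("genome shuffle rejects oversized intervals and preserves lengths", {
  genome <- c(chr1 = 1000)
  expect_error(genome_shuffle_test(gintervals("chr1", 0, 2000),
                                   gintervals("chr1", 0, 10), genome, 10),
               "longer")
})

test_that("planted breakpoint enrichment is detected by the shuffle test", {
  # hotspots cover 0.5% of the genome; 20 of 100 breakpoints planted inside
  set.seed(54)
  genome <- c(chr1 = 10e6)
  hot_starts <- seq(0, 9.9e6, length.out = 25)
  feats <- gintervals("chr1", hot_starts, hot_starts + 2000)
  inside <- floor(runif(20, 0, 25))
  q_in <- gintervals("chr1", hot_starts[inside + 1] + 500,
                     hot_starts[inside + 1] + 1000)
  q_bg_start <- runif(80, 0, 10e6 - 500)
  q <- rbind(q_in, gintervals("chr1", q_bg_start, q_bg_start + 500))
  r <- genome_shuffle_test(q, feats, genome, iterations = 1000, seed = 7)
  expect_lte(r$p_value, 0.001)
})

test_that("within-gene shuffling preserves containment, counts and lengths", {
  set.seed(55)
  genes <- gene_table("chr1", c(0, 50000), c(20000, 150000))
  peaks <- gintervals("chr1", c(1000, 60000, 300000), c(3000, 62000, 301000))
  for (it in 1:50) {
    sh <- shuffle_within_genes(peaks, genes, seed = it)
    expect_equal(nrow(sh), 3)
    expect_equal(sh$end - sh$start, peaks$end - peaks$start)
    # hosted peaks stay inside their gene
    expect_true(sh$start[1] >= 0 && sh$end[1] <= 20000)
    expect_true(sh$start[2] >= 50000 && sh$end[2] <= 150000)
    expect_true(sh$shuffled[1] && sh$shuffled[2])
    # orphan peak is left in place and flagged
    expect_equal(sh$start[3], 300000)
    expect_false(sh$shuffled[3])
  }
})

test_that("a peak as long as its gene cannot move", {
  genes <- gene_table("chr1", 1000, 2000)
  peaks <- gintervals("chr1", 1000, 2000)
  sh <- shuffle_within_genes(peaks, genes, seed = 1)
  expect_equal(sh$start, 1000)
  expect_equal(sh$end, 2000)
})

test_that("shuffled starts are uniform within the host gene", {
  genes <- gene_table("chr1", 100000, 200000)
  peaks <- gintervals("chr1", 120000, 122000)
  starts <- vapply(1:1000, function(i)
    shuffle_within_genes(peaks, genes, seed = i)$start, numeric(1))
  ks <- suppressWarnings(
    stats::ks.test(starts, "punif", 100000, 198000))
  expect_gt(ks$p.value, 0.01)
})
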