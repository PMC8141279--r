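toy_genome <- function(lens) {
  structure(list(chrom_names = names(lens),
                 chrom_lengths = lens,
                 cpg_positions = lapply(lens, function(l) integer(0)),
                 sequence = NULL), class = "genome_model")
}

test_that("merge_peaks coalesces overlapping and book-ended intervals", {
  a <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  b <- data.frame(chrom = "chr1", start = 15L, end = 30L)
  expect_identical(merge_peaks(a, b),
                   data.frame(chrom = "chr1", start = 10L, end = 30L,
                              stringsAsFactors = FALSE))
  b2 <- data.frame(chrom = "chr1", start = 20L, end = 30L)
  expect_identical(merge_peaks(a, b2)$end, 30L)
  expect_error(merge_peaks(data.frame(chrom = "chr1", start = 5L, end = 5L)),
               "invalid peak")
})

test_that("merge_peaks matches the per-base oracle and is idempotent/commutative", {
  for (s in 1:4) {
    set.seed(500 + s)
    mk <- function(n) {
      st <- sample.int(4000L, n)
      data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE), start = st,
                 end = st + sample.int(300L, n), stringsAsFactors = FALSE)
    }
    a <- mk(120); b <- mk(130)
    m <- merge_peaks(a, b)
    expect_identical(m, oracle_merge(rbind(a, b)))
    expect_identical(merge_peaks(m), m)
    expect_identical(merge_peaks(b, a), m)
  }
})

test_that("window overlap uses half-open bedtools-window semantics", {
  dml <- data.frame(chrom = "chr1", pos = 100L)  # 0-based point 99
  peak <- data.frame(chrom = "chr1", start = 150L, end = 200L)
  expect_identical(window_overlap_count(dml, peak, 50)$n_overlap, 0L)
  expect_identical(window_overlap_count(dml, peak, 51)$n_overlap, 1L)
  inside <- data.frame(chrom = "chr1", pos = 160L)
  expect_identical(window_overlap_count(inside, peak, 0)$n_overlap, 1L)
})

test_that("window overlap equals the all-pairs oracle and is monotone in w", {
  for (s in 1:3) {
    set.seed(600 + s)
    dml <- data.frame(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                      pos = sample.int(200000L, 500))
    st <- sample.int(200000L, 80)
    peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 80, TRUE),
                        start = st, end = st + sample.int(800L, 80))
    got <- window_overlap_count(dml, peaks, c(0L, 500L, 10000L))
    for (k in 1:3) {
      expect_identical(got$n_overlap[k],
                       oracle_window_count(dml, peaks, got$w[k]))
    }
    expect_true(all(diff(got$n_overlap) >= 0))
  }
})

test_that("shuffle preserves lengths, is deterministic and places uniformly", {
  gm <- toy_genome(c(chr1 = 100000L, chr2 = 50000L))
  set.seed(1)
  st <- sample.int(90000L, 60)
  peaks <- data.frame(chrom = "chr1", start = st, end = st + sample.int(500L, 60))
  s1 <- shuffle_intervals(peaks, gm, seed = 4)
  s2 <- shuffle_intervals(peaks, gm, seed = 4)
  expect_identical(s1, s2)
  expect_identical(sort(s1$end - s1$start), sort(peaks$end - peaks$start))

  # uniform start on one chromosome: mean start near (L - len) / 2
  one <- toy_genome(c(chr1 = 1000L))
  pk <- data.frame(chrom = "chr1", start = rep(0L, 4000), end = rep(100L, 4000))
  sh <- shuffle_intervals(pk, one, seed = 8)
  expect_true(all(sh$end <= 1000L))
  se <- sqrt((901^2 - 1) / 12) / sqrt(4000)
  expect_lt(abs(mean(sh$start) - 900 / 2), 3 * se)

  # chromosome chosen proportionally to length (2:1 here)
  sh2 <- shuffle_intervals(peaks[rep(1, 3000), ], gm, seed = 9)
  frac1 <- mean(sh2$chrom == "chr1")
  expect_lt(abs(frac1 - 2 / 3), 3 * sqrt(2 / 9 / 3000) + 0.01)

  too_long <- data.frame(chrom = "chr1", start = 0L, end = 2000000L)
  expect_error(shuffle_intervals(too_long, gm), "longer than every chromosome")
})

test_that("permutation p is 1 when the observed overlap is unbeatable-low", {
  gm <- toy_genome(c(chr1 = 10000L, chr2 = 10000L))
  dml <- data.frame(chrom = "chr1", pos = seq(500L, 9500L, by = 200L))
  # real peaks all on chr2; shuffled copies blanket both chromosomes
  st <- seq(0L, 9800L, by = 50L)
  peaks <- data.frame(chrom = "chr2", start = st, end = st + 50L)
  pt <- permutation_overlap_test(dml, peaks, gm, w = 0L, n_perm = 50, seed = 3)
  expect_identical(pt$table$observed, 0L)
  expect_identical(pt$table$p, 1)
})

test_that("empirical permutation p matches exhaustive enumeration on a toy genome", {
  gm <- toy_genome(c(chr1 = 1000L))
  dml <- data.frame(chrom = "chr1", pos = c(100L, 110L, 120L, 500L, 900L))
  peak <- data.frame(chrom = "chr1", start = 95L, end = 125L)  # covers 3 loci
  pt <- permutation_overlap_test(dml, peak, gm, w = 0L, n_perm = 4000, seed = 6)
  obs <- pt$table$observed
  expect_identical(obs, 3L)
  # enumerate every feasible start (uniform over 0..970) and count overlaps
  len <- 30L
  counts <- vapply(0:(1000L - len), function(s) {
    oracle_window_count(dml, data.frame(chrom = "chr1", start = s, end = s + len), 0L)
  }, integer(1))
  p_exact <- mean(counts > obs)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(pt$table$p - p_exact), 3 * se + 1e-9)
})

test_that("zero exceedances are reported as a bounded p string", {
  gm <- toy_genome(c(chr1 = 100000L))
  dml <- data.frame(chrom = "chr1", pos = seq(1000L, 5000L, by = 100L))
  peaks <- data.frame(chrom = "chr1", start = seq(900L, 4900L, by = 100L),
                      end = seq(1100L, 5100L, by = 100L))
  pt <- permutation_overlap_test(dml, peaks, gm, w = 500L, n_perm = 200, seed = 5)
  expect_identical(pt$table$p, 0)
  expect_identical(pt$table$p_reported, "<0.005")
  expect_identical(dim(pt$perm_counts), c(200L, 1L))
})

test_that("aggregate_signal handles constant, empty and random step tracks", {
  anchors <- data.frame(chrom = "chr1", pos = c(3000L, 5000L))
  const <- data.frame(chrom = "chr1", start = 0L, end = 10000L, value = 5)
  prof <- aggregate_signal(const, anchors, flank = 1000, n_bins = 10)
  expect_true(all(prof$matrix == 5))
  expect_identical(prof$mean_profile, rep(5, 10))

  prof0 <- aggregate_signal(const[0, ], anchors, flank = 1000, n_bins = 10)
  expect_true(all(prof0$matrix == 0))

  # per-base oracle on a random step track
  set.seed(77)
  st <- seq(0L, 7800L, by = 200L)
  track <- data.frame(chrom = "chr1", start = st, end = st + 150L,
                      value = round(runif(length(st), 0, 10), 2))
  anc <- data.frame(chrom = "chr1", pos = sample(1500:6500, 20))
  got <- aggregate_signal(track, anc, flank = 400, n_bins = 8)
  want <- oracle_aggregate(track, anc, 400L, 8L)
  expect_equal(got$matrix, want, tolerance = 1e-9)

  # truncated windows are flagged and padded with zeros
  edge <- data.frame(chrom = "chr1", pos = 100L)
  pe <- aggregate_signal(const, edge, flank = 1000, n_bins = 10)
  expect_true(pe$truncated[1])
  expect_identical(pe$matrix[1, 1], 0)
})

test_that("anchor-level signal comparison matches the textbook t statistic", {
  a <- list(matrix = matrix(c(0, 0, 0, 0), 4, 1))
  b <- list(matrix = matrix(c(1, 1, 1, 1) + c(0.01, -0.01, 0.02, -0.02), 4, 1))
  cmp <- compare_anchor_signal(a, b)
  expect_lt(cmp$p, 0.01)

  ident <- compare_anchor_signal(b, b)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  set.seed(9)
  x <- matrix(rnorm(40), 10, 4); y <- matrix(rnorm(40, 0.5), 10, 4)
  cmp2 <- compare_anchor_signal(list(matrix = x), list(matrix = y))
  xa <- rowMeans(x); yb <- rowMeans(y)
  sp <- sqrt(((9 * var(xa)) + (9 * var(yb))) / 18)
  t_oracle <- (mean(xa) - mean(yb)) / (sp * sqrt(2 / 10))
  expect_equal(cmp2$t, t_oracle, tolerance = 1e-10)
  expect_equal(cmp2$p, 2 * pt(-abs(t_oracle), 18), tolerance = 1e-10)
  expect_error(compare_anchor_signal(list(matrix = x[1, , drop = FALSE]),
                                     list(matrix = y[1, , drop = FALSE])),
               ">= 2 anchors")
})
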