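test_that("method-of-moments dispersion matches hand arithmetic", {
  # replicates (3/10, 7/10) vs (5/10, 5/10)
  mm <- matrix_from_counts(rbind(c(3L, 7L, 5L, 5L)), rbind(c(10L, 10L, 10L, 10L)),
                           c("CD8", "CD8", "DN", "DN"))
  d <- estimate_dispersions(mm)
  # group means 0.5/0.5; SS = 0.04 + 0.04; binomial part a = 4 * 0.025;
  # coefficient b = 4 * 0.25 * 9/10; phi = (0.08 - 0.1) / 0.9 < 0 -> clamp
  expect_identical(d$phi_raw, 0)

  mm2 <- matrix_from_counts(rbind(c(0L, 10L, 5L, 5L)), rbind(c(10L, 10L, 10L, 10L)),
                            c("CD8", "CD8", "DN", "DN"))
  d2 <- estimate_dispersions(mm2)
  ss <- (0 - 0.5)^2 + (1 - 0.5)^2
  a <- 4 * (0.25 / 10)
  b <- 4 * (0.25 * 9 / 10)
  expect_equal(d2$phi_raw, (ss - a) / b, tolerance = 1e-12)
})

test_that("degenerate zero-variance matrices fall back to the documented prior", {
  meth <- matrix(5L, 20, 6); total <- matrix(10L, 20, 6)
  mm <- matrix_from_counts(meth, total, rep(c("CD8", "DN"), each = 3))
  d <- estimate_dispersions(mm)
  expect_true(all(d$phi_raw == 0))
  expect_identical(d$m0, log(0.01))
  expect_true(all(d$phi_shrunk == exp(log(0.01))))
})

test_that("dispersion estimation recovers a simulated phi and shrinks toward the prior", {
  gm <- build_genome(1, 1e6, 0.01, seed = 19, with_sequence = FALSE)
  sim <- simulate_methylomes(gm, NULL,
                             sim_config(mean_coverage = 30, phi = 0.02, seed = 19))
  mm <- coverage_filter(sim$methylomes, min_cov = 10)
  d <- estimate_dispersions(mm)
  expect_gte(mean(d$phi_shrunk), 0.01)
  expect_lte(mean(d$phi_shrunk), 0.04)
  # shrinkage property: log phi moves toward m0, never past the raw value
  ok <- is.finite(d$phi_raw) & d$phi_raw > 0
  expect_true(all(abs(log(d$phi_shrunk[ok]) - d$m0) <=
                    abs(log(d$phi_raw[ok]) - d$m0) + 1e-12))
})

test_that("wald test returns delta 0, t 0, p 1 for identical pooled counts", {
  meth <- matrix(c(3L, 4L, 5L, 3L, 4L, 5L), 1, 6)
  total <- matrix(10L, 1, 6)
  mm <- matrix_from_counts(meth, total, rep(c("CD8", "DN"), each = 3))
  wt <- wald_test(mm, estimate_dispersions(mm))
  expect_identical(wt$delta, 0)
  expect_identical(wt$stat, 0)
  expect_identical(wt$pvalue, 1)
})

test_that("wald statistic matches an independent recomputation of the formulas", {
  meth <- rbind(c(30L, 30L, 30L, 3L, 3L, 3L))
  total <- matrix(30L, 1, 6)
  mm <- matrix_from_counts(meth, total, rep(c("CD8", "DN"), each = 3))
  disp <- estimate_dispersions(mm)
  disp$phi_shrunk <- 0.01  # pin the dispersion so the oracle is closed-form
  wt <- wald_test(mm, disp)
  # oracle: straight transcription of the estimator definitions
  phi <- 0.01
  mu1 <- 90 / 90; mu2 <- 9 / 90
  vw <- 3 * 30 * (1 + 29 * phi) / 90^2
  v1 <- mu1 * (1 - mu1) * vw            # 0: CD8 is degenerate at 1
  v2 <- mu2 * (1 - mu2) * vw
  delta <- mu2 - mu1
  t_oracle <- delta / sqrt(v1 + v2)
  expect_equal(wt$delta, delta, tolerance = 1e-12)
  expect_equal(wt$stat, t_oracle, tolerance = 1e-12)
  expect_equal(wt$pvalue, 2 * pnorm(-abs(t_oracle)), tolerance = 1e-12)
})

test_that("fully degenerate variances use the continuity correction, not infinity", {
  meth <- rbind(c(10L, 10L, 10L, 0L, 0L, 0L))
  total <- matrix(10L, 1, 6)
  mm <- matrix_from_counts(meth, total, rep(c("CD8", "DN"), each = 3))
  wt <- wald_test(mm, estimate_dispersions(mm))
  expect_true(is.finite(wt$stat))
  expect_lt(wt$stat, 0)
  expect_gt(wt$pvalue, 0)
})

test_that("swapping group labels flips delta and t but not p", {
  gm <- build_genome(1, 50000, 0.01, seed = 23, with_sequence = FALSE)
  dmr <- data.frame(chrom = "chr1", start = 10000L, end = 15000L,
                    direction = "hypo", delta = -0.4, baseline = 0.8)
  sim <- simulate_methylomes(gm, dmr, sim_config(seed = 23))
  mm <- coverage_filter(sim$methylomes, min_cov = 10)
  disp <- estimate_dispersions(mm)
  fwd <- wald_test(mm, disp, reference = "CD8", case = "DN")
  rev <- wald_test(mm, disp, reference = "DN", case = "CD8")
  expect_equal(rev$delta, -fwd$delta, tolerance = 1e-12)
  expect_equal(rev$stat, -fwd$stat, tolerance = 1e-12)
  expect_equal(rev$pvalue, fwd$pvalue, tolerance = 1e-12)
  expect_true(all(fwd$pvalue > 0 & fwd$pvalue <= 1))
})

test_that("bh_fdr reproduces the step-up oracle exactly", {
  expect_identical(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  for (s in 1:5) {
    set.seed(100 + s)
    p <- runif(200)^2
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    expect_true(all(bh_fdr(p) >= p))
  }
  expect_error(bh_fdr(c(0.5, NA)), "NA")
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("call_dml applies strict thresholds and summarises direction", {
  tab <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L), strand = "+",
                    mu_ref = c(0.9, 0.9, 0.5), mu_case = c(0.7, 0.4, 0.8),
                    delta = c(-0.20, -0.5, 0.3), stat = c(-5, -9, 4),
                    pvalue = c(1e-6, 1e-12, 1e-4), stringsAsFactors = FALSE)
  res <- call_dml(tab)
  # |delta| = 0.20 exactly fails the strict > rule despite tiny FDR
  expect_false(res$table$significant[1])
  expect_true(res$table$significant[2])
  expect_identical(res$table$direction[2], "hypo")
  expect_identical(res$summary$n_hypo, 1L)
  expect_identical(res$summary$n_hyper, 1L)
  expect_error(call_dml(tab, fdr_threshold = 1.5), "fdr_threshold")
  expect_error(call_dml(tab, min_delta = 0), "min_delta")
})

test_that("significance profile reports the per-window minimum p", {
  tab <- data.frame(chrom = "chr1", pos = c(150L, 180L, 1200L), strand = "+",
                    mu_ref = 0.5, mu_case = 0.5, delta = 0,
                    stat = 0, pvalue = c(0.5, 1e-8, 0.2),
                    stringsAsFactors = FALSE)
  prof <- chromosome_significance_profile(tab, 1000)
  expect_identical(nrow(prof), 2L)
  expect_identical(prof$min_p, c(1e-8, 0.2))
  expect_identical(prof$start, c(0L, 1000L))
  # windows holding a spiked DMR rank lower in min-p than flanking windows
  gm <- build_genome(1, 200000, 0.01, seed = 27, with_sequence = FALSE)
  dmr <- data.frame(chrom = "chr1", start = 100000L, end = 104000L,
                    direction = "hypo", delta = -0.5, baseline = 0.9)
  sim <- simulate_methylomes(gm, dmr, sim_config(seed = 27))
  mm <- coverage_filter(sim$methylomes)
  wt <- wald_test(mm, estimate_dispersions(mm))
  p2 <- chromosome_significance_profile(wt, 4000)
  dmr_win <- p2$start == 100000L
  expect_true(any(dmr_win))
  expect_lt(max(p2$min_p[dmr_win]), min(p2$min_p[!dmr_win]))
})

test_that("volcano table is a pure projection", {
  tab <- data.frame(chrom = "chr1", pos = 1:3 * 100L, strand = "+",
                    mu_ref = 0.5, mu_case = 0.5,
                    delta = c(-0.5, 0.1, 0), stat = 0,
                    pvalue = c(0.001, 0.5, 1), stringsAsFactors = FALSE)
  res <- call_dml(tab)
  v <- volcano_table(res)
  expect_identical(nrow(v), 3L)
  expect_equal(v$neglog10_fdr[res$table$fdr == 1], 0)
  i <- which(res$table$delta == -0.5)
  expect_equal(v$neglog10_fdr[i], -log10(res$table$fdr[i]))
})
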