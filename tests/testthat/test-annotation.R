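test_that("nearest TSS picks the closest gene and breaks ties lexicographically", {
  tss <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                    tss = c(900L, 1200L), stringsAsFactors = FALSE)
  ann <- nearest_tss(data.frame(chrom = "chr1", pos = 1000L), tss)
  expect_identical(ann$gene, "g1")
  expect_identical(ann$distance, 100L)

  tie <- data.frame(gene = c("B", "A"), chrom = "chr1",
                    tss = c(900L, 1100L), stringsAsFactors = FALSE)
  ann2 <- nearest_tss(data.frame(chrom = "chr1", pos = 1000L), tie)
  expect_identical(ann2$gene, "A")

  # same-position ties also resolve on gene id
  dup <- data.frame(gene = c("zz", "aa"), chrom = "chr1",
                    tss = c(500L, 500L), stringsAsFactors = FALSE)
  ann3 <- nearest_tss(data.frame(chrom = "chr1", pos = 480L), dup)
  expect_identical(ann3$gene, "aa")
})

test_that("nearest TSS agrees with the exhaustive all-pairs scan", {
  for (s in 1:3) {
    set.seed(400 + s)
    dml <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                      pos = sample.int(100000L, 300), stringsAsFactors = FALSE)
    tss <- data.frame(gene = sprintf("g%03d", 1:60),
                      chrom = sample(c("chr1", "chr2"), 60, TRUE),
                      tss = sample.int(100000L, 60), stringsAsFactors = FALSE)
    got <- nearest_tss(dml, tss)
    want <- oracle_nearest(dml, tss)
    expect_identical(got$gene, want$gene)
    expect_identical(got$distance, want$distance)
  }
})

test_that("loci on chromosomes without a TSS stay unannotated", {
  tss <- data.frame(gene = "g1", chrom = "chr1", tss = 100L,
                    stringsAsFactors = FALSE)
  expect_message(
    ann <- nearest_tss(data.frame(chrom = c("chr1", "chrX"), pos = c(50L, 50L)), tss),
    "unannotated")
  expect_identical(ann$gene, c("g1", NA))
  expect_error(nearest_tss(data.frame(chrom = "chr1", pos = 1L), tss[0, ]), "empty")
})

test_that("expression integration counts genes, DML and quadrants", {
  ann <- data.frame(chrom = "chr1", pos = c(100L, 200L), strand = "+",
                    delta = c(-0.5, -0.4), direction = "hypo",
                    gene = "g1", distance = c(10L, 110L),
                    stringsAsFactors = FALSE)
  expr0 <- data.frame(gene = "g1", lfc = 2, pvalue = 0.001, upregulated = FALSE)
  i0 <- integrate_expression(ann, expr0)
  expect_identical(i0$n_up_genes_with_hypo_dml, 0L)

  expr1 <- transform(expr0, upregulated = TRUE)
  i1 <- integrate_expression(ann, expr1)
  expect_identical(i1$n_up_genes_with_hypo_dml, 1L)
  expect_identical(i1$n_dml_at_up_genes, 2L)
  expect_identical(i1$n_hypo_dml_at_up_genes, 2L)
  expect_identical(unname(i1$quadrants["hypo_up"]), 2L)
  expect_identical(sum(i1$quadrants), 2L)
  expect_error(integrate_expression(ann, expr1[0, ]), "empty")
})

test_that("integration counts are invariant to row order of either table", {
  set.seed(11)
  ann <- data.frame(chrom = "chr1", pos = 1:20 * 50L, strand = "+",
                    delta = runif(20, -0.6, 0.3),
                    gene = sample(paste0("g", 1:6), 20, TRUE),
                    stringsAsFactors = FALSE)
  ann$direction <- ifelse(ann$delta < 0, "hypo", "hyper")
  expr <- data.frame(gene = paste0("g", 1:6), lfc = rnorm(6),
                     pvalue = runif(6), upregulated = c(TRUE, TRUE, FALSE,
                                                        TRUE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  a <- integrate_expression(ann, expr)
  b <- integrate_expression(ann[sample(20), ], expr[sample(6), ])
  expect_identical(a$n_up_genes_with_hypo_dml, b$n_up_genes_with_hypo_dml)
  expect_identical(a$n_dml_at_up_genes, b$n_dml_at_up_genes)
  expect_identical(a$quadrants, b$quadrants)
})

test_that("coupled simulations enrich the demethylated-upregulated quadrant", {
  gm <- build_genome(1, 1e6, 0.005, seed = 41, with_sequence = FALSE)
  dmrs <- simulate_dmr_specs(gm, 40, 1500, hypo_fraction = 1, seed = 41)
  sim <- simulate_methylomes(gm, dmrs, sim_config(seed = 41))
  genes <- simulate_genes(gm, 300, seed = 42)
  ann <- nearest_tss(sim$truth[, c("chrom", "pos", "delta", "direction")], genes)
  frac_ul <- vapply(1:3, function(s) {
    e <- simulate_expression(genes, sim$truth, coupling = 0.8, seed = s)
    ic <- integrate_expression(ann, e)
    ic$quadrants[["hypo_up"]] / sum(ic$quadrants)
  }, numeric(1))
  frac_null <- vapply(1:3, function(s) {
    e <- simulate_expression(genes, sim$truth, coupling = 0, seed = s)
    ic <- integrate_expression(ann, e)
    ic$quadrants[["hypo_up"]] / sum(ic$quadrants)
  }, numeric(1))
  expect_true(all(frac_ul > frac_null))
})

test_that("gene ranking orders by hypo-DML count with deterministic ties", {
  joined <- data.frame(gene = c("geneA", "geneA", "geneA", "geneB"),
                       delta = -0.5, upregulated = TRUE,
                       stringsAsFactors = FALSE)
  r <- rank_genes_by_dml(joined)
  expect_identical(r$gene, c("geneA", "geneB"))
  expect_identical(r$n_hypo_dml, c(3L, 1L))

  tie <- data.frame(gene = c("B", "B", "A", "A"), delta = -0.5,
                    upregulated = TRUE, stringsAsFactors = FALSE)
  expect_identical(rank_genes_by_dml(tie)$gene, c("A", "B"))
  # counts sum to the number of ranked DML (each DML has one nearest gene)
  expect_identical(sum(rank_genes_by_dml(tie)$n_hypo_dml), 4L)
})

test_that("the gene beside the largest spiked DMR ranks first", {
  gm <- build_genome(1, 1e6, 0.01, seed = 43, with_sequence = FALSE)
  dmrs <- rbind(
    data.frame(chrom = "chr1", start = 100000L, end = 130000L,
               direction = "hypo", delta = -0.5, baseline = 0.9),
    data.frame(chrom = "chr1", start = 600000L, end = 601000L,
               direction = "hypo", delta = -0.5, baseline = 0.9))
  sim <- simulate_methylomes(gm, dmrs, sim_config(mean_coverage = 30, seed = 43))
  genes <- data.frame(gene = c("big", "small", "far"), chrom = "chr1",
                      tss = c(115000L, 600500L, 300000L), strand = "+",
                      stringsAsFactors = FALSE)
  mm <- coverage_filter(sim$methylomes)
  dml <- call_dml(wald_test(mm, estimate_dispersions(mm)))
  ann <- nearest_tss(significant_dml(dml), genes)
  r <- rank_genes_by_dml(ann, upregulated_only = FALSE)
  expect_identical(r$gene[1], "big")
})
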