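#' Default pipeline configuration
#'
#' One nested list holds every tunable of the end-to-end run. Analysis
#' thresholds default to the standard values of the workflow the package
#' implements (coverage >= 10 per group, FDR < 0.05, |delta| > 0.20,
#' overlap windows 0/500/1000/5000/10000 bp, 1000 permutations, 400 bp
#' motif windows, 2 kb signal flanks); simulation sizes default to a small
#' single-chromosome genome that runs in well under two minutes.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "rrbsdml_run",
    genome = list(n_chroms = 1L, chrom_length_bp = 1e6, cpg_density = 0.005,
                  with_sequence = TRUE),
    dmr = list(n_dmr = 40L, dmr_length_bp = 1000L, hypo_fraction = 0.96,
               delta_mag = 0.5, baseline_hypo = 0.9, baseline_hyper = 0.1),
    methylome = list(n_replicates = 3L, mean_coverage = 20, coverage_size = 5,
                     phi = 0.02, baseline_weight_low = 0.3,
                     baseline_shape1 = 3, baseline_shape2 = 39),
    spikein = list(n_sites = 1000L, depth = 50L, conversion_rate = 0.995,
                   threshold = 0.99),
    peaks = list(enrich_frac = 0.9, max_offset = 500L, peak_len_min = 200L,
                 peak_len_max = 600L, n_background = 100L, n_naive = 100L,
                 signal_baseline = 1, signal_effect = 5, bin = 50L),
    expression = list(n_genes = 200L, coupling = 0.8, up_lfc = 1, up_p = 0.05,
                      null_sd = 0.5),
    filter = list(min_cov = 10L, per_sample = FALSE),
    dml = list(fdr = 0.05, min_delta = 0.20,
               profile_windows_bp = c(10000L, 100000L)),
    enrich = list(windows = c(0L, 500L, 1000L, 5000L, 10000L),
                  n_perm = 1000L, flank = 2000L, n_bins = 40L),
    motifs = list(flank = 200L, planting_rate = 0.8,
                  planted_consensus = "TGACTCA", bg_per_fg = 2L,
                  min_bg_dist = 1000L, max_fg = 500L)
  )
}

#' Validate a pipeline configuration
#'
#' Merges the supplied list (or YAML file) over \code{\link{default_config}}
#' and checks every field that has a constrained range, failing with a
#' field-level message before any computation.
#'
#' @param config A nested list or the path of a YAML file.
#' @return The merged, validated configuration.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_param("config must be a list or a YAML file path")
  cfg <- utils::modifyList(default_config(), config)
  chk <- function(val, lo, hi, field, open = FALSE) {
    bad <- !is.numeric(val) || length(val) == 0 ||
      (if (open) any(val <= lo | val >= hi) else any(val < lo | val > hi))
    if (bad) stop_param("config field `%s` must lie in %s%g, %g%s", field,
                        if (open) "(" else "[", lo, hi,
                        if (open) ")" else "]")
  }
  chk(cfg$dml$fdr, 0, 1, "dml.fdr", open = TRUE)
  chk(cfg$dml$min_delta, 0, 1, "dml.min_delta", open = TRUE)
  chk(cfg$filter$min_cov, 1, Inf, "filter.min_cov")
  chk(cfg$methylome$phi, 0, 0.999, "methylome.phi")
  chk(cfg$dmr$hypo_fraction, 0, 1, "dmr.hypo_fraction")
  chk(cfg$peaks$enrich_frac, 0, 1, "peaks.enrich_frac")
  chk(cfg$expression$coupling, 0, 1, "expression.coupling")
  chk(cfg$enrich$n_perm, 1, Inf, "enrich.n_perm")
  chk(cfg$enrich$windows, 0, Inf, "enrich.windows")
  chk(cfg$spikein$conversion_rate, 1e-12, 1, "spikein.conversion_rate")
  chk(cfg$motifs$flank, 10, Inf, "motifs.flank")
  cfg
}

#' Run the full pipeline
#'
#' Simulates every input (genome, DMR truth, replicated methylomes,
#' spike-in, peak sets, signal tracks, genes, expression), then runs the
#' analysis chain: coverage filter and conversion QC, beta-binomial Wald
#' DML calling, nearest-TSS annotation and expression integration,
#' permutation peak-proximity enrichment, anchored signal comparison and
#' motif enrichment. Every stage's artifact is written under
#' \code{out_dir} as plain text, and a JSON manifest records the config,
#' seed and an MD5 digest of every file, so a rerun with the same config is
#' byte-identical (timestamps excluded).
#'
#' @param config Nested list or YAML path (see \code{\link{validate_config}}).
#' @param out_dir Output directory (overrides \code{config$out_dir}).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every in-memory stage result and
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  cfg <- validate_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- cfg$seed
  pathof <- function(f) file.path(cfg$out_dir, f)

  ## stage 1: simulate -------------------------------------------------
  gm <- do.call(build_genome, c(cfg$genome, list(seed = derive_seed(seed, "genome"))))
  dmrs <- do.call(simulate_dmr_specs,
                  c(list(genome = gm), cfg$dmr, list(seed = derive_seed(seed, "dmr"))))
  scfg <- do.call(sim_config, c(cfg$methylome, list(seed = seed)))
  sim <- simulate_methylomes(gm, dmrs, scfg)
  say("simulate: %d CpG sites, %d truth DML (%d hypo)",
      sum(lengths(gm$cpg_positions)), nrow(sim$truth),
      sum(sim$truth$direction == "hypo"))
  spike <- simulate_spikein(cfg$spikein$n_sites, cfg$spikein$depth,
                            cfg$spikein$conversion_rate,
                            seed = derive_seed(seed, "spikein"))
  pk <- simulate_peaks_and_signal(gm, sim$truth, cfg$peaks,
                                  seed = derive_seed(seed, "peaks"))
  genes <- simulate_genes(gm, cfg$expression$n_genes,
                          seed = derive_seed(seed, "genes"))
  expr <- simulate_expression(genes, sim$truth, cfg$expression$coupling,
                              seed = derive_seed(seed, "expression"),
                              up_lfc = cfg$expression$up_lfc,
                              up_p = cfg$expression$up_p,
                              null_sd = cfg$expression$null_sd)
  if (cfg$genome$with_sequence && cfg$motifs$planting_rate > 0 &&
      nrow(sim$truth)) {
    hypo_anchors <- sim$truth[sim$truth$direction == "hypo", c("chrom", "pos")]
    pm <- plant_motifs(gm, hypo_anchors, cfg$motifs$planted_consensus,
                       planting_rate = cfg$motifs$planting_rate,
                       window = cfg$motifs$flank,
                       seed = derive_seed(seed, "motifs"))
    gm <- pm$genome
    write_tsv(pm$log, pathof("motif_planting_log.tsv"))
  }
  for (m in sim$methylomes) {
    write_cytosine_report(m, pathof(sprintf("methylome_%s.txt", m$sample_id)))
  }
  write_tsv(sim$truth, pathof("truth_dml.tsv"))
  write_tsv(spike, pathof("spikein.tsv"))
  write_bed(pk$naive_peaks, pathof("naive_peaks.bed"))
  write_bed(pk$effector_peaks, pathof("effector_peaks.bed"))
  write_bedgraph(pk$naive_track, pathof("naive_signal.bedgraph"))
  write_bedgraph(pk$effector_track, pathof("effector_signal.bedgraph"))
  write_tsv(genes, pathof("genes.tsv"))
  write_tsv(expr, pathof("expression.tsv"))
  if (cfg$genome$with_sequence) write_genome_fasta(gm, pathof("genome.fa"))

  ## stage 2: filter + QC ----------------------------------------------
  conv <- conversion_efficiency(spike, threshold = cfg$spikein$threshold)
  say("qc: conversion efficiency %.4f (pass: %s)",
      conv$efficiency[1], conv$pass[1])
  mm <- coverage_filter(sim$methylomes, min_cov = cfg$filter$min_cov,
                        per_sample = cfg$filter$per_sample)
  say("filter: %d of %d CpG retained at >= %d reads per group",
      mm$n_retained, mm$n_input, cfg$filter$min_cov)
  gsum <- global_methylation_summary(mm)
  say("global methylation: CD8 - DN difference = %.4f", gsum$difference)
  write_tsv(conv, pathof("conversion_efficiency.tsv"))
  write_tsv(gsum$per_sample, pathof("global_methylation.tsv"))

  ## stage 3: DML calling ----------------------------------------------
  disp <- estimate_dispersions(mm)
  wt <- wald_test(mm, disp)
  dml <- call_dml(wt, fdr_threshold = cfg$dml$fdr, min_delta = cfg$dml$min_delta)
  say("dml: %d significant of %d tested (%.1f%% hypo)",
      dml$summary$n_significant, dml$summary$n_tested,
      100 * (dml$summary$hypo_fraction %||% NA_real_))
  write_tsv(dml$table, pathof("dml_table.tsv"))
  for (wbp in cfg$dml$profile_windows_bp) {
    prof <- chromosome_significance_profile(wt, wbp)
    write_bedgraph(prof[, c("chrom", "start", "end", "value")],
                   pathof(sprintf("significance_profile_%dbp.bedgraph", wbp)))
  }
  write_tsv(volcano_table(dml), pathof("volcano.tsv"))
  sig <- significant_dml(dml)

  ## stage 4: annotate + integrate --------------------------------------
  ann <- nearest_tss(sig, genes)
  integ <- integrate_expression(ann, expr)
  ranks <- rank_genes_by_dml(integ$joined)
  say("integrate: %d upregulated genes with >= 1 hypo DML; %d/%d DML at upregulated genes are hypo",
      integ$n_up_genes_with_hypo_dml, integ$n_hypo_dml_at_up_genes,
      integ$n_dml_at_up_genes)
  write_tsv(integ$joined, pathof("annotated_dml.tsv"))
  write_tsv(ranks, pathof("gene_ranks.tsv"))
  jsonlite::write_json(list(
    n_up_genes_with_hypo_dml = integ$n_up_genes_with_hypo_dml,
    n_dml_at_up_genes = integ$n_dml_at_up_genes,
    n_hypo_dml_at_up_genes = integ$n_hypo_dml_at_up_genes,
    quadrants = as.list(integ$quadrants)),
    pathof("integration_summary.json"), auto_unbox = TRUE, digits = NA)

  ## stage 5: interval enrichment ---------------------------------------
  merged <- merge_peaks(pk$naive_peaks, pk$effector_peaks)
  perm <- permutation_overlap_test(sig, merged, gm, w = cfg$enrich$windows,
                                   n_perm = cfg$enrich$n_perm,
                                   seed = derive_seed(seed, "perm"))
  say("enrich: observed overlap at w=500 is %d (p %s)",
      perm$table$observed[perm$table$w == 500][1] %||% NA_integer_,
      perm$table$p_reported[perm$table$w == 500][1] %||% "NA")
  write_tsv(perm$table, pathof("permutation_test.tsv"))
  write_tsv(as.data.frame(perm$perm_counts), pathof("permutation_counts.tsv"))
  jsonlite::write_json(perm$table, pathof("permutation_test.json"),
                       auto_unbox = TRUE, digits = NA)
  sig_hypo <- sig[sig$direction == "hypo", , drop = FALSE]
  cmp <- NULL
  if (nrow(sig_hypo) >= 2L) {
    prof_n <- aggregate_signal(pk$naive_track, sig_hypo,
                               flank = cfg$enrich$flank, n_bins = cfg$enrich$n_bins)
    prof_e <- aggregate_signal(pk$effector_track, sig_hypo,
                               flank = cfg$enrich$flank, n_bins = cfg$enrich$n_bins)
    cmp <- compare_anchor_signal(prof_e, prof_n)
    say("signal: effector %.3f vs naive %.3f around hypo DML (t = %.2f, p = %.3g)",
        cmp$mean_a, cmp$mean_b, cmp$t, cmp$p)
    write_tsv(data.frame(offset = prof_n$bin_centers,
                         naive = prof_n$mean_profile,
                         effector = prof_e$mean_profile),
              pathof("signal_profiles.tsv"))
  }

  ## stage 6: motifs -----------------------------------------------------
  motif_res <- NULL
  if (cfg$genome$with_sequence && nrow(sig_hypo) >= 5L) {
    fg_anchors <- sig_hypo[, c("chrom", "pos")]
    if (nrow(fg_anchors) > cfg$motifs$max_fg) {
      fg_anchors <- fg_anchors[seq_len(cfg$motifs$max_fg), , drop = FALSE]
    }
    fg <- extract_windows(gm, fg_anchors, flank = cfg$motifs$flank)
    bg <- sample_background_windows(gm, fg_anchors,
                                    n = cfg$motifs$bg_per_fg * nrow(fg_anchors),
                                    flank = cfg$motifs$flank,
                                    min_dist = cfg$motifs$min_bg_dist,
                                    seed = derive_seed(seed, "motif_bg"))
    pwms <- bundled_pwms()
    motif_res <- motif_enrichment(fg, bg, pwms)
    say("motifs: top motif %s (p = %.3g)", motif_res$motif[1], motif_res$p[1])
    write_tsv(motif_res, pathof("motif_enrichment.tsv"))
    top <- pwms[[motif_res$motif[1]]]
    hits <- scan_pwm(fg, top)
    if (nrow(hits)) {
      profs <- motif_centered_profiles(hits, mm,
                                       tracks = list(naive = pk$naive_track,
                                                     effector = pk$effector_track),
                                       flank = cfg$motifs$flank)
      write_tsv(profs, pathof("motif_profiles.tsv"))
    }
  }

  ## manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    tool = paste0("rrbsdml ", as.character(utils::packageVersion("rrbsdml"))),
    seed = seed,
    config = cfg,
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(pathof(f))), bytes = file.size(pathof(f)))
    }),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, pathof("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(config = cfg, genome = gm, dmrs = dmrs, sim = sim,
                 spikein = spike, peaks = pk, genes = genes,
                 expression = expr, conversion = conv, matrix = mm,
                 global_summary = gsum, dispersions = disp, wald = wt,
                 dml = dml, annotation = ann, integration = integ,
                 gene_ranks = ranks, permutation = perm, signal = cmp,
                 motifs = motif_res, manifest = manifest))
}
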