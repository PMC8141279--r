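#' Simulation configuration
#'
#' Collects every tunable of the methylome simulator in one validated list.
#' Defaults emulate the study design the pipeline targets: two groups
#' ("CD8" precursors and "DN" cases) of three replicate purifications each,
#' overdispersed RRBS-like coverage, a bimodal genome-wide baseline
#' methylation distribution, and a beta-binomial replicate dispersion.
#'
#' @param n_replicates Replicates per group (default 3).
#' @param mean_coverage Mean per-replicate CpG coverage (default 20). Coverage
#'   is drawn as 1 + NegBin(mu = mean_coverage - 1, size = coverage_size), so
#'   it is overdispersed with a hard minimum of one read.
#' @param coverage_size Negative-binomial size (inverse overdispersion) of the
#'   coverage distribution (default 5).
#' @param phi Beta-binomial dispersion of replicate methylation proportions
#'   (default 0.02); \code{phi = 0} gives plain binomial counts.
#' @param baseline_weight_low Mixture weight of the low-methylation component
#'   (default 0.3).
#' @param baseline_shape1,baseline_shape2 Shape parameters of the
#'   low-methylation Beta component (default Beta(3, 39), mode 0.05); the
#'   high component is its mirror Beta(39, 3), mode 0.95.
#' @param seed Master seed; every generator draws from a named substream
#'   derived from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_replicates = 3L, mean_coverage = 20, coverage_size = 5,
                       phi = 0.02, baseline_weight_low = 0.3,
                       baseline_shape1 = 3, baseline_shape2 = 39, seed = 1L) {
  cfg <- list(n_replicates = as.integer(n_replicates),
              mean_coverage = mean_coverage, coverage_size = coverage_size,
              phi = phi, baseline_weight_low = baseline_weight_low,
              baseline_shape1 = baseline_shape1,
              baseline_shape2 = baseline_shape2, seed = as.integer(seed))
  if (cfg$n_replicates < 1L) stop_param("need >= 1 replicate per group")
  if (cfg$mean_coverage < 1) stop_param("`mean_coverage` must be >= 1")
  if (cfg$phi < 0 || cfg$phi >= 1) stop_param("`phi` must be in [0, 1)")
  if (cfg$baseline_weight_low < 0 || cfg$baseline_weight_low > 1) {
    stop_param("`baseline_weight_low` must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Generate non-overlapping differentially methylated region (DMR) specs
#'
#' Places \code{n_dmr} fixed-length regions uniformly on the genome without
#' overlap, assigns each a direction by the hypo:hyper mixture, and gives it
#' a baseline (reference-group) methylation and a target difference
#' \code{delta} (DN minus CD8; negative for hypomethylation).
#'
#' @param genome A \code{genome_model}.
#' @param n_dmr Number of regions.
#' @param dmr_length_bp Region length (bp).
#' @param hypo_fraction Fraction of regions that lose methylation in the case
#'   group (default 0.96, the direction asymmetry the simulator emulates).
#' @param delta_mag Magnitude of the methylation difference (default 0.5).
#' @param baseline_hypo Baseline (CD8) methylation of hypo regions
#'   (default 0.9, so the case group drops to 0.4).
#' @param baseline_hyper Baseline of hyper regions (default 0.1).
#' @param seed Integer seed.
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   direction ("hypo"/"hyper"), delta, baseline.
#' @export
simulate_dmr_specs <- function(genome, n_dmr = 40L, dmr_length_bp = 1000L,
                               hypo_fraction = 0.96, delta_mag = 0.5,
                               baseline_hypo = 0.9, baseline_hyper = 0.1,
                               seed = 1L) {
  validate_genome(genome)
  n_dmr <- as.integer(n_dmr)
  if (n_dmr < 1L) stop_param("`n_dmr` must be >= 1")
  lens <- genome$chrom_lengths
  if (n_dmr * dmr_length_bp * 2 > sum(as.numeric(lens))) {
    stop_param("requested DMRs exceed genome capacity")
  }
  with_seed(seed, {
    placed <- list()
    occ <- lapply(genome$chrom_names, function(ch) matrix(numeric(0), ncol = 2))
    names(occ) <- genome$chrom_names
    k <- 0L; tries <- 0L
    while (k < n_dmr && tries < 50L * n_dmr) {
      tries <- tries + 1L
      ch <- sample(genome$chrom_names, 1L, prob = as.numeric(lens))
      s <- sample.int(lens[[ch]] - dmr_length_bp, 1L) - 1L
      e <- s + dmr_length_bp
      o <- occ[[ch]]
      if (nrow(o) == 0L || all(e <= o[, 1] | s >= o[, 2])) {
        occ[[ch]] <- rbind(o, c(s, e))
        k <- k + 1L
        placed[[k]] <- data.frame(chrom = ch, start = s, end = e,
                                  stringsAsFactors = FALSE)
      }
    }
    if (k < n_dmr) stop_param("could not place %d non-overlapping DMRs", n_dmr)
    d <- do.call(rbind, placed)
    hypo <- runif(n_dmr) < hypo_fraction
    d$direction <- ifelse(hypo, "hypo", "hyper")
    d$delta <- ifelse(hypo, -delta_mag, delta_mag)
    d$baseline <- ifelse(hypo, baseline_hypo, baseline_hyper)
    d <- d[order(d$chrom, d$start), ]
    rownames(d) <- NULL
    validate_dmr_specs(d, genome)
    d
  })
}

validate_dmr_specs <- function(dmrs, genome) {
  if (nrow(dmrs) == 0L) return(invisible(dmrs))
  stopifnot(all(c("chrom", "start", "end", "direction", "delta", "baseline")
                %in% names(dmrs)))
  if (any(dmrs$start >= dmrs$end)) stop_param("DMR with start >= end")
  if (!all(dmrs$chrom %in% genome$chrom_names)) {
    stop_param("DMR on unknown chromosome")
  }
  if (any(dmrs$start < 0) ||
      any(dmrs$end > genome$chrom_lengths[dmrs$chrom])) {
    stop_param("DMR outside genome bounds")
  }
  if (any(dmrs$baseline < 0 | dmrs$baseline > 1)) stop_param("baseline outside [0, 1]")
  if (any(dmrs$direction == "hypo" & dmrs$delta > 0) ||
      any(dmrs$direction == "hyper" & dmrs$delta < 0)) {
    stop_param("DMR direction inconsistent with the sign of delta")
  }
  shifted <- dmrs$baseline + dmrs$delta
  if (any(shifted < 0 | shifted > 1)) {
    stop_param("baseline + delta leaves [0, 1] for a DMR")
  }
  # overlapping DMRs with conflicting direction are rejected
  for (ch in unique(dmrs$chrom)) {
    d <- dmrs[dmrs$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1L) {
      ov <- which(d$start[-1] < d$end[-nrow(d)])
      if (length(ov) && any(d$direction[ov] != d$direction[ov + 1L])) {
        stop_param("overlapping DMRs with conflicting direction on %s", ch)
      }
    }
  }
  invisible(dmrs)
}

# Draw beta-binomial counts with mean mu and dispersion phi given totals N.
rbetabinom <- function(n, N, mu, phi) {
  mu <- rep_len(mu, n); N <- rep_len(N, n)
  if (phi <= 0) return(rbinom(n, N, mu))
  ab <- 1 / phi - 1
  p <- rbeta(n, mu * ab, (1 - mu) * ab)
  # guard against degenerate shape parameters at mu = 0 or 1
  p[mu == 0] <- 0; p[mu == 1] <- 1
  rbinom(n, N, p)
}

#' Simulate replicated methylomes with spiked DMRs
#'
#' Draws, for every CpG of the genome, per-replicate coverage and
#' beta-binomially distributed methylated counts for the two groups. Outside
#' DMRs both groups share a baseline drawn from the bimodal Beta mixture of
#' \code{\link{sim_config}}; inside a DMR the CD8 group sits at the DMR's
#' baseline and the DN group is shifted by the DMR's \code{delta}.
#'
#' @param genome A \code{genome_model}.
#' @param dmrs DMR spec data.frame (possibly empty) as from
#'   \code{\link{simulate_dmr_specs}}.
#' @param config A \code{\link{sim_config}}.
#' @return list with \code{methylomes} (list of \code{methylome} objects,
#'   samples CD8_1..n then DN_1..n) and \code{truth} (data.frame of every CpG
#'   inside a DMR with nonzero delta: chrom, pos, mu_cd8, mu_dn, delta,
#'   direction).
#' @export
simulate_methylomes <- function(genome, dmrs, config = sim_config()) {
  validate_genome(genome)
  stopifnot(inherits(config, "sim_config"))
  if (is.null(dmrs)) dmrs <- empty_dmr_specs()
  validate_dmr_specs(dmrs, genome)
  seed <- derive_seed(config$seed, "methylomes")
  with_seed(seed, {
    chrom <- rep(genome$chrom_names, lengths(genome$cpg_positions))
    pos <- unlist(genome$cpg_positions, use.names = FALSE)
    n <- length(pos)
    if (n == 0L) stop_param("genome has no CpG sites")
    low <- runif(n) < config$baseline_weight_low
    mu <- ifelse(low,
                 rbeta(n, config$baseline_shape1, config$baseline_shape2),
                 rbeta(n, config$baseline_shape2, config$baseline_shape1))
    mu_cd8 <- mu; mu_dn <- mu
    in_dmr <- rep(FALSE, n)
    if (nrow(dmrs)) {
      for (i in seq_len(nrow(dmrs))) {
        # DMR coords are 0-based half-open; CpG pos is 1-based
        idx <- which(chrom == dmrs$chrom[i] &
                       pos - 1L >= dmrs$start[i] & pos - 1L < dmrs$end[i])
        mu_cd8[idx] <- dmrs$baseline[i]
        mu_dn[idx] <- dmrs$baseline[i] + dmrs$delta[i]
        in_dmr[idx] <- in_dmr[idx] | (dmrs$delta[i] != 0)
      }
    }
    nr <- config$n_replicates
    draw_sample <- function(mu_vec) {
      N <- 1L + as.integer(rnbinom(n, mu = config$mean_coverage - 1,
                                   size = config$coverage_size))
      X <- rbetabinom(n, N, mu_vec, config$phi)
      data.frame(chrom = chrom, pos = pos, strand = "+",
                 n_meth = X, n_total = N, stringsAsFactors = FALSE)
    }
    meths <- c(
      lapply(seq_len(nr), function(r) {
        new_methylome(draw_sample(mu_cd8), sprintf("CD8_%d", r), "CD8")
      }),
      lapply(seq_len(nr), function(r) {
        new_methylome(draw_sample(mu_dn), sprintf("DN_%d", r), "DN")
      })
    )
    truth <- data.frame(chrom = chrom[in_dmr], pos = pos[in_dmr],
                        mu_cd8 = mu_cd8[in_dmr], mu_dn = mu_dn[in_dmr],
                        delta = mu_dn[in_dmr] - mu_cd8[in_dmr],
                        stringsAsFactors = FALSE)
    truth$direction <- ifelse(truth$delta < 0, "hypo", "hyper")
    list(methylomes = meths, truth = truth)
  })
}

empty_dmr_specs <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             direction = character(0), delta = numeric(0),
             baseline = numeric(0), stringsAsFactors = FALSE)
}

#' Simulate a fully methylated spike-in conversion control
#'
#' Emulates a methylated spike-in read out at unmethylated-context cytosines:
#' each site receives \code{depth} reads and a converted count drawn
#' Binomial(depth, conversion_rate).
#'
#' @param n_sites Number of control cytosines (> 0).
#' @param depth Reads per site (>= 1).
#' @param conversion_rate True bisulfite conversion probability in (0, 1].
#' @param seed Integer seed.
#' @return data.frame with columns site, converted, total.
#' @export
simulate_spikein <- function(n_sites, depth, conversion_rate, seed = 1L) {
  if (!is.numeric(n_sites) || n_sites < 1) {
    stop_param("`n_sites` must be >= 1 (efficiency is undefined otherwise)")
  }
  if (depth < 1) stop_param("`depth` must be >= 1")
  if (conversion_rate <= 0 || conversion_rate > 1) {
    stop_param("`conversion_rate` must be in (0, 1]")
  }
  n_sites <- as.integer(n_sites)
  with_seed(seed, {
    data.frame(site = sprintf("spike_%05d", seq_len(n_sites)),
               converted = rbinom(n_sites, as.integer(depth), conversion_rate),
               total = as.integer(depth), stringsAsFactors = FALSE)
  })
}

#' Simulate accessibility peak sets and signal tracks
#'
#' Places "effector" peaks preferentially near true DMLs (each truth DML
#' receives, with probability \code{enrich_frac}, a peak whose centre lies
#' within \code{max_offset} bp of it) plus uniform background peaks, and a
#' "naive" peak set placed uniformly. Produces one bedGraph-style signal
#' track per condition: gamma-distributed background noise, elevated by
#' \code{signal_effect} inside that condition's peaks.
#'
#' @param genome A \code{genome_model}.
#' @param dml_truth Truth table from \code{\link{simulate_methylomes}} (may
#'   have zero rows).
#' @param params list with elements \code{enrich_frac} (default 0.9),
#'   \code{max_offset} (500), \code{peak_len_min} (200), \code{peak_len_max}
#'   (600), \code{n_background} (100), \code{n_naive} (100),
#'   \code{signal_baseline} (1), \code{signal_effect} (5), \code{bin} (50).
#' @param seed Integer seed.
#' @return list with \code{naive_peaks}, \code{effector_peaks} (BED-style
#'   data.frames: chrom, start, end, name) and \code{naive_track},
#'   \code{effector_track} (data.frames: chrom, start, end, value).
#' @export
simulate_peaks_and_signal <- function(genome, dml_truth, params = list(), seed = 1L) {
  validate_genome(genome)
  p <- utils::modifyList(list(enrich_frac = 0.9, max_offset = 500L,
                              peak_len_min = 200L, peak_len_max = 600L,
                              n_background = 100L, n_naive = 100L,
                              signal_baseline = 1, signal_effect = 5,
                              bin = 50L), params)
  if (p$enrich_frac < 0 || p$enrich_frac > 1) stop_param("`enrich_frac` must be in [0, 1]")
  lens <- genome$chrom_lengths
  capacity <- sum(as.numeric(lens)) / mean(c(p$peak_len_min, p$peak_len_max))
  if (p$n_background + p$n_naive + nrow(dml_truth) > capacity) {
    stop_param("requested peak count exceeds genome capacity")
  }
  with_seed(seed, {
    rand_peaks <- function(k, tag) {
      if (k == 0L) return(empty_peaks())
      ch <- sample(genome$chrom_names, k, replace = TRUE, prob = as.numeric(lens))
      len <- sample(p$peak_len_min:p$peak_len_max, k, replace = TRUE)
      start <- vapply(seq_len(k), function(i) {
        sample.int(lens[[ch[i]]] - len[i], 1L) - 1L
      }, integer(1))
      data.frame(chrom = ch, start = start, end = start + len,
                 name = sprintf("%s_%04d", tag, seq_len(k)),
                 stringsAsFactors = FALSE)
    }
    eff_near <- empty_peaks()
    if (nrow(dml_truth)) {
      take <- runif(nrow(dml_truth)) < p$enrich_frac
      anchors <- dml_truth[take, , drop = FALSE]
      if (nrow(anchors)) {
        len <- sample(p$peak_len_min:p$peak_len_max, nrow(anchors), replace = TRUE)
        centre <- pos_to_point0(anchors$pos) +
          sample(seq(-p$max_offset, p$max_offset), nrow(anchors), replace = TRUE)
        start <- pmax(0L, as.integer(centre - len %/% 2L))
        end <- pmin(as.integer(lens[anchors$chrom]), start + len)
        keep <- end > start
        eff_near <- data.frame(chrom = anchors$chrom[keep], start = start[keep],
                               end = end[keep],
                               name = sprintf("eff_dml_%04d", which(keep)),
                               stringsAsFactors = FALSE)
      }
    }
    effector <- rbind(eff_near, rand_peaks(p$n_background, "eff_bg"))
    effector <- effector[order(effector$chrom, effector$start), ]
    rownames(effector) <- NULL
    naive <- rand_peaks(p$n_naive, "naive")
    naive <- naive[order(naive$chrom, naive$start), ]
    rownames(naive) <- NULL
    make_track <- function(peaks) {
      rows <- lapply(genome$chrom_names, function(ch) {
        L <- lens[[ch]]
        start <- seq(0L, L - 1L, by = p$bin)
        end <- pmin(start + p$bin, L)
        value <- rgamma(length(start), shape = 2, rate = 2 / p$signal_baseline)
        pk <- peaks[peaks$chrom == ch, , drop = FALSE]
        if (nrow(pk)) {
          mid <- (start + end) / 2
          inside <- vapply(mid, function(m) any(m >= pk$start & m < pk$end), logical(1))
          value[inside] <- value[inside] + p$signal_effect
        }
        data.frame(chrom = ch, start = start, end = end, value = value,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    list(naive_peaks = naive, effector_peaks = effector,
         naive_track = make_track(naive), effector_track = make_track(effector))
  })
}

empty_peaks <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), stringsAsFactors = FALSE)
}

#' Simulate a gene (TSS) table
#'
#' Uniformly placed single-TSS genes with lexicographically ordered ids.
#'
#' @param genome A \code{genome_model}.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return data.frame with columns gene, chrom, tss (1-based), strand.
#' @export
simulate_genes <- function(genome, n_genes = 200L, seed = 1L) {
  validate_genome(genome)
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop_param("`n_genes` must be >= 1")
  lens <- genome$chrom_lengths
  with_seed(seed, {
    ch <- sample(genome$chrom_names, n_genes, replace = TRUE,
                 prob = as.numeric(lens))
    tss <- vapply(ch, function(c) sample.int(lens[[c]], 1L), integer(1))
    g <- data.frame(gene = sprintf("gene%05d", seq_len(n_genes)), chrom = ch,
                    tss = tss, strand = sample(c("+", "-"), n_genes, TRUE),
                    stringsAsFactors = FALSE)
    g[order(g$gene), ]
  })
}

#' Simulate an expression table coupled to demethylation
#'
#' Genes whose TSS is the nearest to at least one hypomethylated truth DML
#' are, with probability \code{coupling}, given an unambiguous positive log
#' fold change (above \code{up_lfc}) and a small p-value (below
#' \code{up_p}); all other genes draw from a zero-centred null. The
#' \code{upregulated} flag applies the stated thresholds to every gene.
#'
#' @param gene_table data.frame as from \code{\link{simulate_genes}}.
#' @param dml_truth Truth table; its hypo rows are the demethylation anchors.
#' @param coupling Probability in [0, 1] that a DML-adjacent gene is
#'   upregulated.
#' @param seed Integer seed.
#' @param up_lfc,up_p Thresholds defining "upregulated" (defaults 1 and 0.05).
#' @param null_sd Standard deviation of the null log fold change (default 0.5).
#' @return data.frame with columns gene, lfc, pvalue, upregulated,
#'   dml_adjacent.
#' @export
simulate_expression <- function(gene_table, dml_truth, coupling = 0.8, seed = 1L,
                                up_lfc = 1, up_p = 0.05, null_sd = 0.5) {
  if (is.null(gene_table) || nrow(gene_table) == 0L) {
    stop_param("`gene_table` must be non-empty")
  }
  if (anyDuplicated(gene_table$gene)) stop_param("gene ids must be unique")
  if (coupling < 0 || coupling > 1) stop_param("`coupling` must be in [0, 1]")
  hypo <- dml_truth[dml_truth$direction == "hypo", , drop = FALSE]
  adjacent <- character(0)
  if (nrow(hypo)) {
    ann <- nearest_tss(hypo, gene_table)
    adjacent <- unique(ann$gene[!is.na(ann$gene)])
  }
  n <- nrow(gene_table)
  with_seed(seed, {
    lfc <- rnorm(n, 0, null_sd)
    pval <- runif(n)
    is_adj <- gene_table$gene %in% adjacent
    coupled <- is_adj & runif(n) < coupling
    k <- sum(coupled)
    if (k) {
      lfc[coupled] <- up_lfc + 0.5 + abs(rnorm(k, 0, 0.5))
      pval[coupled] <- runif(k, 1e-8, up_p / 2)
    }
    data.frame(gene = gene_table$gene, lfc = lfc, pvalue = pval,
               upregulated = lfc > up_lfc & pval < up_p,
               dml_adjacent = is_adj, stringsAsFactors = FALSE)
  })
}
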