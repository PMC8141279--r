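#' Construct a position weight matrix
#'
#' @param name Motif name.
#' @param matrix Numeric matrix, 4 rows named A, C, G, T, one column per
#'   motif position; each column must sum to 1.
#' @param pseudocount Added to every probability before log-odds scoring
#'   (default 0.01).
#' @param background Background base frequencies (A, C, G, T), default
#'   uniform.
#' @param threshold Score threshold as a fraction of the maximum attainable
#'   log-odds, in (0, 1] (default 0.8).
#' @return Object of class \code{pwm}.
#' @export
pwm <- function(name, matrix, pseudocount = 0.01,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                threshold = 0.8) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L) stop_param("PWM must have 4 rows (A, C, G, T)")
  rownames(m) <- c("A", "C", "G", "T")
  if (any(abs(colSums(m) - 1) > 1e-9)) stop_param("PWM columns must sum to 1")
  if (threshold <= 0 || threshold > 1) stop_param("`threshold` must be in (0, 1]")
  structure(list(name = name, matrix = m, pseudocount = pseudocount,
                 background = background, threshold = threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s, threshold %.2f x max\n",
              x$name, ncol(x$matrix), pwm_consensus(x), x$threshold))
  invisible(x)
}

#' Consensus string of a PWM (most probable base per position)
#' @param x A \code{pwm}.
#' @return Character string.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$matrix)[apply(x$matrix, 2L, which.max)], collapse = "")
}

# Per-position log2-odds score matrix and its attainable maximum.
pwm_score_matrix <- function(x) {
  p <- (x$matrix + x$pseudocount) / (1 + 4 * x$pseudocount)
  log2(p / x$background)
}

#' Build a PWM from a consensus string
#'
#' Each position gives probability \code{1 - 3 * slack} to the consensus
#' base and \code{slack} to the others, a sharp but non-degenerate model.
#'
#' @param name Motif name.
#' @param consensus A/C/G/T string.
#' @param slack Off-consensus probability per base (default 0.02).
#' @param ... Passed to \code{\link{pwm}}.
#' @return A \code{pwm}.
#' @export
pwm_from_consensus <- function(name, consensus, slack = 0.02, ...) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) stop_param("consensus must be A/C/G/T")
  m <- matrix(slack, 4L, length(bases), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- 1 - 3 * slack
  pwm(name, m, ...)
}

#' Bundled PWM library
#'
#' Small library used by the motif-enrichment stage: an AP-1 (TGACTCA)
#' basic-leucine-zipper motif, a T-box (T-BET-style) motif, an EGR
#' zinc-finger motif, and the MspI (CCGG) / TaqI (TCGA) restriction-site
#' "motifs" that act as positive controls in reduced-representation data,
#' where fragment ends are enzymatically enriched for exactly those sites.
#'
#' @param ... Passed to each \code{\link{pwm_from_consensus}} call
#'   (e.g. \code{threshold}).
#' @return Named list of \code{pwm} objects, read from the MEME-format file
#'   shipped with the package.
#' @export
bundled_pwms <- function(...) {
  path <- system.file("extdata", "pwms.meme", package = "rrbsdml")
  read_meme(path, ...)
}

#' Read PWMs from a MEME minimal-format file
#' @param path File path.
#' @param ... Passed to \code{\link{pwm}} (pseudocount, background,
#'   threshold).
#' @return Named list of \code{pwm} objects.
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  heads <- grep("^MOTIF\\s+", lines)
  if (!length(heads)) stop_param("no MOTIF records in %s", path)
  out <- list()
  for (h in heads) {
    name <- strsplit(trimws(lines[h]), "\\s+")[[1]][2]
    ml <- grep("^letter-probability matrix", lines[h:length(lines)])[1] + h - 1L
    wid <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[ml]))
    rows <- lines[(ml + 1L):(ml + wid)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(4), USE.NAMES = FALSE))
    # renormalise against rounding in the text representation
    m <- m / rowSums(m)
    out[[name]] <- pwm(name, t(m), ...)
  }
  out
}

#' Write PWMs to a MEME minimal-format file
#' @param pwms Named list of \code{pwm} objects.
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(p$matrix)), con)
    apply(p$matrix, 2L, function(col) {
      writeLines(paste(formatC(col, digits = 6, format = "f"), collapse = " "), con)
    })
    writeLines("", con)
  }
  invisible(path)
}

#' Extract sequence windows around anchor points
#'
#' @param genome A \code{genome_model} with sequence.
#' @param anchors data.frame with chrom, pos (1-based).
#' @param flank Half-width in bp (default 200, i.e. 400 bp windows).
#' @return data.frame with chrom, start, end (0-based half-open), seq;
#'   windows are truncated at chromosome edges.
#' @export
extract_windows <- function(genome, anchors, flank = 200L) {
  validate_genome(genome)
  if (is.null(genome$sequence)) stop_param("genome has no sequence")
  flank <- as.integer(flank)
  s1 <- pmax(1L, anchors$pos - flank)               # 1-based inclusive
  e1 <- pmin(as.integer(genome$chrom_lengths[anchors$chrom]), anchors$pos + flank - 1L)
  data.frame(chrom = anchors$chrom, start = s1 - 1L, end = e1,
             seq = substring(genome$sequence[anchors$chrom], s1, e1),
             stringsAsFactors = FALSE)
}

#' Scan sequence windows with a PWM
#'
#' Both strands are scored at every offset with additive log2-odds
#' \eqn{\sum_j \log_2(p_j(b_j)/bg(b_j))} (pseudocount-adjusted); positions
#' scoring at least \code{threshold} times the maximal attainable score are
#' reported. Overlapping hits, including the same site on both strands, are
#' all kept. Windows shorter than the motif are skipped.
#'
#' @param windows data.frame as from \code{\link{extract_windows}} (needs
#'   chrom, start, seq).
#' @param pwm A \code{pwm}.
#' @return data.frame with chrom, start, end (0-based half-open, genomic),
#'   strand, name, score, window (input row index).
#' @export
scan_pwm <- function(windows, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  sm <- pwm_score_matrix(pwm)
  L <- ncol(sm)
  max_score <- sum(apply(sm, 2L, max))
  cutoff <- pwm$threshold * max_score
  hits <- list()
  for (i in seq_len(nrow(windows))) {
    s <- toupper(windows$seq[i])
    n <- nchar(s)
    if (n < L) next
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    for (strand in c("+", "-")) {
      v <- if (strand == "+") codes else rev(5L - codes)  # reverse complement
      n_off <- n - L + 1L
      sc <- numeric(n_off)
      ok <- !logical(n_off)
      for (j in seq_len(L)) {
        bj <- v[j:(j + n_off - 1L)]
        nab <- is.na(bj)
        ok <- ok & !nab
        bj[nab] <- 1L
        sc <- sc + sm[cbind(bj, j)]
      }
      pass <- which(ok & sc >= cutoff)
      if (length(pass)) {
        # map scan offsets back to forward-strand genomic coordinates
        off0 <- if (strand == "+") pass - 1L else n - L + 1L - pass
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = windows$chrom[i], start = windows$start[i] + off0,
          end = windows$start[i] + off0 + L, strand = strand,
          name = pwm$name, score = sc[pass], window = i,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0), score = numeric(0),
                      window = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$window, out$start, out$strand), , drop = FALSE]
}

#' Sample background windows for motif enrichment
#'
#' Draws CpG-anchored windows of the same width as the foreground, at least
#' \code{min_dist} bp away from every foreground anchor, matched to the
#' foreground GC-content distribution in quintile bins. CpG anchoring keeps
#' the restriction-site composition of reduced-representation fragments, so
#' enzyme-site artifacts show up honestly in both sets.
#'
#' @param genome A \code{genome_model} with sequence.
#' @param fg_anchors Foreground anchors (chrom, pos).
#' @param n Number of background windows (default twice the foreground).
#' @param flank Half-width (default 200).
#' @param min_dist Minimum distance from any foreground anchor (default 1000).
#' @param seed Integer seed.
#' @return data.frame of windows as from \code{\link{extract_windows}}.
#' @export
sample_background_windows <- function(genome, fg_anchors, n = 2L * nrow(fg_anchors),
                                      flank = 200L, min_dist = 1000L, seed = 1L) {
  validate_genome(genome)
  gc_of <- function(wins) {
    s <- toupper(wins$seq)
    (nchar(gsub("[^GC]", "", s))) / pmax(nchar(s), 1L)
  }
  fg_win <- extract_windows(genome, fg_anchors, flank)
  fg_gc <- gc_of(fg_win)
  br <- unique(stats::quantile(fg_gc, probs = seq(0, 1, 0.2), names = FALSE))
  bin_of <- function(gc) {
    if (length(br) < 3L) rep(1L, length(gc))
    else cut(gc, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  fg_bins <- bin_of(fg_gc)
  target <- tabulate(fg_bins, nbins = max(fg_bins)) / length(fg_bins)
  cand <- do.call(rbind, lapply(genome$chrom_names, function(ch) {
    pos <- genome$cpg_positions[[ch]]
    fg <- fg_anchors$pos[fg_anchors$chrom == ch]
    if (length(fg)) {
      near <- vapply(pos, function(p) any(abs(p - fg) < min_dist), logical(1))
      pos <- pos[!near]
    }
    if (!length(pos)) return(NULL)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) < n) {
    stop_param("not enough CpG-anchored background candidates (have %d, need %d)",
               if (is.null(cand)) 0L else nrow(cand), n)
  }
  cand_win <- extract_windows(genome, cand, flank)
  cand_bins <- bin_of(pmin(pmax(gc_of(cand_win), min(br)), max(br)))
  with_seed(seed, {
    take <- integer(0)
    for (b in seq_along(target)) {
      want <- round(n * target[b])
      pool <- which(cand_bins == b)
      if (length(pool) == 0L) next
      take <- c(take, sample(pool, min(want, length(pool))))
    }
    # top up from the full pool if rounding or thin bins left a shortfall
    if (length(take) < n) {
      rest <- setdiff(seq_len(nrow(cand)), take)
      take <- c(take, sample(rest, min(n - length(take), length(rest))))
    }
    cand_win[sort(take[seq_len(min(n, length(take)))]), , drop = FALSE]
  })
}

#' Motif enrichment of foreground versus background windows
#'
#' A window "contains" a motif if it has at least one PWM hit. Per PWM, the
#' foreground containment count is tested against the background
#' containment fraction with a one-sided binomial test
#' (\eqn{P(X \ge k), X \sim Bin(n_{fg}, p_{bg})}). A background fraction of
#' zero with foreground hits is continuity-corrected to
#' \eqn{1/(2 n_{bg})}. PWMs are ranked by p-value (ties by name).
#'
#' @param fg_windows,bg_windows Window tables (both non-empty).
#' @param pwm_set Named list of \code{pwm} objects (may be empty).
#' @return data.frame with columns motif, fg_hits, fg_n, fg_fraction,
#'   bg_hits, bg_n, bg_fraction, p, rank.
#' @export
motif_enrichment <- function(fg_windows, bg_windows, pwm_set) {
  if (nrow(fg_windows) == 0L || nrow(bg_windows) == 0L) {
    stop_param("foreground and background window sets must be non-empty")
  }
  if (!length(pwm_set)) {
    return(data.frame(motif = character(0), fg_hits = integer(0),
                      fg_n = integer(0), fg_fraction = numeric(0),
                      bg_hits = integer(0), bg_n = integer(0),
                      bg_fraction = numeric(0), p = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(pwm_set, function(p) {
    fg_hit <- length(unique(scan_pwm(fg_windows, p)$window))
    bg_hit <- length(unique(scan_pwm(bg_windows, p)$window))
    n_fg <- nrow(fg_windows); n_bg <- nrow(bg_windows)
    p0 <- bg_hit / n_bg
    if (p0 == 0 && fg_hit > 0) p0 <- 1 / (2 * n_bg)
    pv <- if (p0 >= 1) 1 else stats::pbinom(fg_hit - 1L, n_fg, p0, lower.tail = FALSE)
    data.frame(motif = p$name, fg_hits = fg_hit, fg_n = n_fg,
               fg_fraction = fg_hit / n_fg, bg_hits = bg_hit, bg_n = n_bg,
               bg_fraction = bg_hit / n_bg, p = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$motif), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Methylation and accessibility profiles centred on motif hits
#'
#' For every motif in \code{hits}, reports the mean group-level methylation
#' (pooled counts per group, averaged over CpGs) across all CpGs within
#' \code{flank} bp of a hit midpoint, and the mean accessibility of each
#' supplied signal track over the same windows
#' (via \code{\link{aggregate_signal}}).
#'
#' @param hits Hit table from \code{\link{scan_pwm}} (possibly several
#'   motifs row-bound together).
#' @param mm A \code{meth_matrix}.
#' @param tracks Named list of bedGraph-style data.frames (may be empty).
#' @param flank Half-window in bp (default 200).
#' @return data.frame with one row per motif: motif, n_hits, n_cpgs, one
#'   \code{meth_<group>} column per group and one \code{acc_<track>} column
#'   per track; methylation columns are NA when no CpG falls in any window.
#' @export
motif_centered_profiles <- function(hits, mm, tracks = list(), flank = 200L) {
  if (nrow(hits) == 0L) stop_param("no motif hits supplied")
  stopifnot(inherits(mm, "meth_matrix"))
  groups <- unique(mm$groups)
  rows <- lapply(split(hits, hits$name), function(h) {
    mid <- (h$start + h$end) %/% 2L
    sel <- logical(nrow(mm$keys))
    for (ch in unique(h$chrom)) {
      m <- mid[h$chrom == ch]
      ki <- which(mm$keys$chrom == ch)
      if (!length(ki)) next
      p0 <- pos_to_point0(mm$keys$pos[ki])
      sel[ki] <- vapply(p0, function(p) any(abs(p - m) <= flank), logical(1))
    }
    row <- data.frame(motif = h$name[1], n_hits = nrow(h), n_cpgs = sum(sel),
                      stringsAsFactors = FALSE)
    for (g in groups) {
      cols <- mm$groups == g
      val <- if (any(sel)) {
        fr <- rowSums(mm$meth[sel, cols, drop = FALSE]) /
          rowSums(mm$total[sel, cols, drop = FALSE])
        mean(fr, na.rm = TRUE)
      } else NA_real_
      row[[paste0("meth_", g)]] <- val
    }
    anchors <- data.frame(chrom = h$chrom, pos = mid + 1L,
                          stringsAsFactors = FALSE)
    for (tn in names(tracks)) {
      prof <- aggregate_signal(tracks[[tn]], anchors, flank = flank,
                               n_bins = max(1L, min(20L, flank)))
      row[[paste0("acc_", tn)]] <- mean(prof$matrix)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$n_cpgs == 0L)) {
    message(sprintf("motif_centered_profiles: %d motif(s) had no CpG in any window",
                    sum(out$n_cpgs == 0L)))
  }
  out
}
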