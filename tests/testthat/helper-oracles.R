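# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# BH step-up, literal textbook form.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Nearest TSS by exhaustive all-pairs scan, ties by gene id.
oracle_nearest <- function(dml, tss) {
  res <- lapply(seq_len(nrow(dml)), function(i) {
    t <- tss[tss$chrom == dml$chrom[i], , drop = FALSE]
    if (nrow(t) == 0L) return(data.frame(gene = NA_character_, distance = NA_integer_))
    d <- abs(dml$pos[i] - t$tss)
    cand <- which(d == min(d))
    best <- cand[order(t$gene[cand])][1]
    data.frame(gene = t$gene[best], distance = dml$pos[i] - t$tss[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# DML-in-window count by all-pairs distance check (0-based point vs interval).
oracle_window_count <- function(dml, peaks, w) {
  if (nrow(dml) == 0L || nrow(peaks) == 0L) return(0L)
  hit <- vapply(seq_len(nrow(dml)), function(i) {
    p0 <- dml$pos[i] - 1L
    any(peaks$chrom == dml$chrom[i] &
          p0 >= peaks$start - w & p0 < peaks$end + w)
  }, logical(1))
  sum(hit)
}

# Interval union via a per-base occupancy bitmap (small coordinates only).
oracle_merge <- function(x, max_coord = 5000L) {
  out <- lapply(split(x, x$chrom), function(d) {
    occ <- logical(max_coord)
    for (i in seq_len(nrow(d))) occ[(d$start[i] + 1L):d$end[i]] <- TRUE
    # book-ended intervals are already contiguous in the bitmap
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    data.frame(chrom = d$chrom[1], start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# Per-base averaging of a step track over binned anchor windows.
oracle_aggregate <- function(track, anchors, flank, n_bins) {
  bw <- 2L * flank / n_bins
  mat <- matrix(0, nrow(anchors), n_bins)
  for (i in seq_len(nrow(anchors))) {
    p0 <- anchors$pos[i] - 1L
    base_vals <- numeric(2L * flank)
    for (k in seq_len(2L * flank)) {
      b <- p0 - flank + (k - 1L)       # 0-based base index
      if (b < 0) next
      tr <- track[track$chrom == anchors$chrom[i] &
                    track$start <= b & track$end > b, , drop = FALSE]
      if (nrow(tr)) base_vals[k] <- tr$value[1]
    }
    mat[i, ] <- vapply(seq_len(n_bins), function(bn) {
      mean(base_vals[((bn - 1L) * bw + 1L):(bn * bw)])
    }, numeric(1))
  }
  mat
}

# Random valid methylome for round-trip properties.
random_methylome <- function(n = 50L, seed = 1L, sample_id = "s1", group = "CD8") {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  pos <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sample.int(100000L, length(idx))
  }
  total <- rpois(n, 15) + 1L
  rec <- data.frame(chrom = chrom, pos = pos,
                    strand = sample(c("+", "-"), n, TRUE),
                    n_meth = rbinom(n, total, 0.5), n_total = total,
                    stringsAsFactors = FALSE)
  rec <- rec[!duplicated(rec[c("chrom", "pos", "strand")]), ]
  rrbsdml:::new_methylome(rec, sample_id, group)
}

# Small two-group matrix from explicit count matrices.
matrix_from_counts <- function(meth, total, groups) {
  n <- nrow(meth)
  samples <- paste0(groups, "_", ave(seq_along(groups), groups, FUN = seq_along))
  ms <- lapply(seq_along(groups), function(j) {
    rec <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L, strand = "+",
                      n_meth = meth[, j], n_total = total[, j],
                      stringsAsFactors = FALSE)
    rec <- rec[rec$n_total > 0, , drop = FALSE]
    rrbsdml:::new_methylome(rec, samples[j], groups[j])
  })
  coverage_filter(ms, min_cov = 1L)
}
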