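validate_intervals <- function(x, genome = NULL, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x)) {
    bad <- which(x$start < 0 | x$start >= x$end)
    if (length(bad)) {
      stop_param("invalid %s at %s:%s-%s", what, x$chrom[bad[1]],
                 x$start[bad[1]], x$end[bad[1]])
    }
    if (!is.null(genome)) {
      if (!all(x$chrom %in% genome$chrom_names)) {
        stop_param("%s on unknown chromosome", what)
      }
      if (any(x$end > genome$chrom_lengths[x$chrom])) {
        stop_param("%s beyond chromosome end", what)
      }
    }
  }
  invisible(x)
}

#' Merge two peak sets
#'
#' Union of both interval sets with overlapping or book-ended (touching)
#' intervals coalesced; the result is sorted and the operation is
#' idempotent and commutative. Coordinates are 0-based half-open.
#'
#' @param set_a,set_b BED-style data.frames (chrom, start, end, ...); either
#'   may be empty.
#' @return data.frame with columns chrom, start, end.
#' @export
merge_peaks <- function(set_a, set_b = NULL) {
  x <- rbind(set_a[, c("chrom", "start", "end")],
             if (!is.null(set_b)) set_b[, c("chrom", "start", "end")])
  validate_intervals(x, what = "peak")
  if (nrow(x) == 0L) return(x)
  out <- lapply(split(x, x$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    # sweep: an interval starts a new run iff it begins after the running end
    run_end <- cummax(d$end)
    new_run <- c(TRUE, d$start[-1] > run_end[-nrow(d)])
    grp <- cumsum(new_run)
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), ]
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  rownames(out) <- NULL
  out
}

#' Count loci with a peak within a window
#'
#' bedtools-window semantics: each peak is extended by \code{w} bp on both
#' sides and a locus (a 0-based point, i.e. 1-based position minus one)
#' matches if it falls inside any extended interval. Each locus is counted
#' at most once.
#'
#' @param dml data.frame with columns \code{chrom}, \code{pos} (1-based).
#' @param peaks BED-style data.frame.
#' @param w Window in bp (>= 0); may be a vector, giving one count per
#'   value.
#' @return data.frame with columns w, n_overlap, fraction.
#' @export
window_overlap_count <- function(dml, peaks, w = 0L) {
  validate_intervals(peaks, what = "peak")
  if (any(w < 0)) stop_param("`w` must be >= 0")
  n <- nrow(dml)
  res <- vapply(as.integer(w), function(wi) {
    if (n == 0L || nrow(peaks) == 0L) return(0L)
    ext <- data.frame(chrom = peaks$chrom,
                      start = pmax(0L, peaks$start - wi),
                      end = peaks$end + wi, stringsAsFactors = FALSE)
    m <- merge_peaks(ext)
    hit <- 0L
    for (ch in unique(dml$chrom)) {
      p0 <- pos_to_point0(dml$pos[dml$chrom == ch])
      mc <- m[m$chrom == ch, , drop = FALSE]
      if (nrow(mc) == 0L) next
      # merged intervals are disjoint and sorted: point inside iff the
      # latest start <= p0 has end > p0
      j <- findInterval(p0, mc$start)
      inside <- j >= 1L & p0 < mc$end[pmax(j, 1L)]
      hit <- hit + sum(inside)
    }
    hit
  }, integer(1))
  data.frame(w = as.integer(w), n_overlap = res,
             fraction = if (n) res / n else rep(NA_real_, length(w)))
}

#' Shuffle intervals across the genome
#'
#' bedtools-shuffle semantics: every interval keeps its length and is
#' re-placed uniformly at random, the chromosome drawn with probability
#' proportional to its length (among chromosomes long enough to hold the
#' interval) and the start uniform over the feasible range. Shuffled
#' intervals may overlap each other.
#'
#' @param peaks BED-style data.frame.
#' @param genome A \code{genome_model} (only chromosome lengths are used).
#' @param seed Integer seed.
#' @return Shuffled data.frame (chrom, start, end), sorted.
#' @export
shuffle_intervals <- function(peaks, genome, seed = 1L) {
  validate_intervals(peaks, what = "peak")
  lens <- genome$chrom_lengths
  len <- peaks$end - peaks$start
  if (nrow(peaks) && max(len) > max(lens)) {
    stop_param("an interval is longer than every chromosome")
  }
  with_seed(seed, shuffle_intervals_impl(len, lens))
}

# RNG-consuming core, callable inside an existing stream (permutation loop).
shuffle_intervals_impl <- function(len, lens) {
  k <- length(len)
  if (k == 0L) return(empty_peaks()[, c("chrom", "start", "end")])
  chroms <- names(lens)
  pl <- as.numeric(lens)
  ch <- character(k); start <- integer(k)
  # group intervals by length feasibility only when needed (equal-length
  # chromosomes, the common simulated case, take the fast path)
  feasible_all <- min(pl) >= max(len)
  if (feasible_all) {
    ci <- sample.int(length(chroms), k, replace = TRUE, prob = pl)
    ch <- chroms[ci]
    start <- as.integer(floor(stats::runif(k) * (pl[ci] - len + 1)))
  } else {
    for (i in seq_len(k)) {
      ok <- pl >= len[i]
      ci <- sample(which(ok), 1L, prob = pl[ok])
      ch[i] <- chroms[ci]
      start[i] <- as.integer(floor(stats::runif(1) * (pl[ci] - len[i] + 1)))
    }
  }
  out <- data.frame(chrom = ch, start = start, end = start + len,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Permutation test of locus-peak proximity
#'
#' Observed statistic: the number of loci with a peak within \code{w} bp
#' (\code{\link{window_overlap_count}}). Null: the peak set is re-placed
#' uniformly across the genome \code{n_perm} times
#' (\code{\link{shuffle_intervals}}) and the count recomputed. The
#' empirical p-value is the fraction of permutations whose count strictly
#' exceeds the observed one; when that fraction is zero the p-value is
#' reported as \code{"<1/n_perm"} (stored numerically as 0).
#'
#' @param dml Locus table (chrom, pos).
#' @param peaks BED-style peak set.
#' @param genome A \code{genome_model}.
#' @param w Vector of window distances in bp (the distance series is run in
#'   one call over the same permutations).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Object of class \code{perm_test}: list with \code{table}
#'   (data.frame w, observed, fraction, p, p_reported), \code{perm_counts}
#'   (n_perm x length(w) matrix), \code{n_perm}.
#' @export
permutation_overlap_test <- function(dml, peaks, genome, w = c(0L, 500L, 1000L, 5000L, 10000L),
                                     n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) stop_param("`n_perm` must be >= 1")
  validate_intervals(peaks, genome, what = "peak")
  n_perm <- as.integer(n_perm)
  obs <- window_overlap_count(dml, peaks, w)
  len <- peaks$end - peaks$start
  lens <- genome$chrom_lengths
  perm <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      shuf <- shuffle_intervals_impl(len, lens)
      window_overlap_count(dml, shuf, w)$n_overlap
    }, integer(length(w))))
  })
  if (length(w) == 1L) perm <- matrix(perm, ncol = 1L)
  exceed <- colSums(perm > matrix(obs$n_overlap, n_perm, length(w), byrow = TRUE))
  p <- exceed / n_perm
  tab <- data.frame(w = obs$w, observed = obs$n_overlap,
                    fraction = obs$fraction, p = p,
                    p_reported = ifelse(exceed == 0L,
                                        sprintf("<%g", 1 / n_perm),
                                        formatC(p, digits = 4, format = "g")),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, perm_counts = perm, n_perm = n_perm),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %d permutations\n", x$n_perm))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Aggregate a signal track around anchor points
#'
#' Splits the window [pos - flank, pos + flank) around each anchor into
#' \code{n_bins} equal bins and computes, per bin, the coverage-weighted
#' mean of the track value (bases not covered by any track interval count
#' as 0). Windows truncated by a chromosome edge are padded with zeros and
#' flagged.
#'
#' @param track bedGraph-style data.frame (chrom, start, end, value),
#'   non-overlapping within chromosome.
#' @param anchors data.frame with columns chrom, pos (1-based points).
#' @param flank Half-window in bp (default 2000).
#' @param n_bins Number of bins (default 40).
#' @return list with \code{matrix} (anchors x bins), \code{mean_profile}
#'   (length n_bins), \code{bin_centers} (offsets relative to the anchor)
#'   and \code{truncated} (logical per anchor).
#' @export
aggregate_signal <- function(track, anchors, flank = 2000L, n_bins = 40L) {
  validate_intervals(track, what = "track interval")
  flank <- as.integer(flank); n_bins <- as.integer(n_bins)
  if (n_bins < 1L || flank < n_bins) stop_param("need flank >= n_bins >= 1")
  if (2L * flank %% n_bins != 0L) {
    stop_param("2 * flank must be divisible by n_bins")
  }
  n <- nrow(anchors)
  mat <- matrix(0, n, n_bins)
  trunc <- logical(n)
  bw <- 2L * flank / n_bins
  for (ch in unique(anchors$chrom)) {
    idx <- which(anchors$chrom == ch)
    tc <- track[track$chrom == ch, , drop = FALSE]
    tc <- tc[order(tc$start), , drop = FALSE]
    if (nrow(tc) > 1L && any(tc$start[-1] < tc$end[-nrow(tc)])) {
      stop_param("track intervals overlap on %s", ch)
    }
    # cumulative integral of the step function: F(x) = integral_0^x value,
    # exact for piecewise-constant tracks, so bin means need no per-base loop
    cum <- c(0, cumsum(tc$value * (tc$end - tc$start)))
    Fx <- function(x) {
      if (nrow(tc) == 0L) return(numeric(length(x)))
      j <- findInterval(x, tc$start)
      out <- numeric(length(x))
      pos <- j >= 1L
      out[pos] <- cum[j[pos]] + tc$value[j[pos]] *
        pmax(0, pmin(x[pos], tc$end[j[pos]]) - tc$start[j[pos]])
      out
    }
    p0 <- pos_to_point0(anchors$pos[idx])
    trunc[idx] <- p0 - flank < 0
    edges <- outer(p0 - flank, bw * (0:n_bins), `+`)  # (length(idx)) x (n_bins+1)
    vals <- matrix(Fx(pmax(as.vector(edges), 0)), nrow = length(idx))
    mat[idx, ] <- (vals[, -1, drop = FALSE] - vals[, -(n_bins + 1L), drop = FALSE]) / bw
  }
  list(matrix = mat, mean_profile = colMeans(mat),
       bin_centers = seq(-flank + bw / 2, flank - bw / 2, by = bw),
       truncated = trunc)
}

#' Compare per-anchor signal between two conditions
#'
#' Reduces each anchor's profile to its window mean and compares the two
#' conditions with an equal-variance two-sample two-tailed Student t test.
#'
#' @param profiles_a,profiles_b Outputs of \code{\link{aggregate_signal}}
#'   over the same anchors.
#' @return list with \code{mean_a}, \code{mean_b}, \code{per_anchor}
#'   (data.frame a, b), \code{t}, \code{p}.
#' @export
compare_anchor_signal <- function(profiles_a, profiles_b) {
  a <- rowMeans(profiles_a$matrix); b <- rowMeans(profiles_b$matrix)
  if (length(a) != length(b)) stop_param("anchor sets differ between conditions")
  if (length(a) < 2L) stop_param("need >= 2 anchors for a t test")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(mean_a = mean(a), mean_b = mean(b),
       per_anchor = data.frame(a = a, b = b),
       t = unname(tt$statistic), p = tt$p.value)
}

#' Coordinate liftover hook
#'
#' The synthetic pipeline lives in a single coordinate system, so this is
#' an identity pass-through kept for API symmetry with workflows whose peak
#' atlas and methylome were mapped to different assemblies.
#'
#' @param intervals BED-style data.frame.
#' @param chain Ignored.
#' @return \code{intervals}, unchanged.
#' @export
liftover_identity <- function(intervals, chain = NULL) intervals
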