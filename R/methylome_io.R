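new_methylome <- function(records, sample_id, group) {
  m <- structure(list(sample_id = sample_id, group = group,
                      records = records), class = "methylome")
  validate_methylome(m)
}

validate_methylome <- function(m) {
  stopifnot(inherits(m, "methylome"))
  r <- m$records
  need <- c("chrom", "pos", "strand", "n_meth", "n_total")
  if (!all(need %in% names(r))) stop_param("methylome records lack required columns")
  if (nrow(r)) {
    if (!is_count(r$n_meth) || !is_count(r$n_total)) {
      stop_param("methylation counts must be non-negative integers")
    }
    if (any(r$n_meth > r$n_total)) stop_param("n_meth exceeds n_total")
    if (any(r$pos <= 0)) stop_param("positions must be >= 1")
    key <- paste(r$chrom, r$pos, r$strand)
    if (anyDuplicated(key)) stop_param("duplicate (chrom, pos, strand) in methylome")
    ord <- order(r$chrom, r$pos)
    if (!identical(ord, seq_len(nrow(r)))) m$records <- r[ord, , drop = FALSE]
    rownames(m$records) <- NULL
  }
  m
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> sample %s (group %s): %d CpG records\n",
              x$sample_id, x$group, nrow(x$records)))
  invisible(x)
}

#' Read a Bismark-style cytosine report
#'
#' Parses a tab-separated cytosine report with columns chromosome, 1-based
#' position, strand (+/-), methylated count, unmethylated count and an
#' optional context column. Malformed lines raise an error naming the first
#' offending line number.
#'
#' @param path File path.
#' @param sample_id Sample identifier to attach.
#' @param group Group label to attach ("CD8" or "DN" in the two-group design).
#' @return A \code{methylome} object (empty file gives zero records).
#' @export
read_cytosine_report <- function(path, sample_id = basename(path), group = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_methylome(data.frame(chrom = character(0), pos = integer(0),
                                    strand = character(0), n_meth = integer(0),
                                    n_total = integer(0), stringsAsFactors = FALSE),
                         sample_id, group))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 5L)
  if (length(bad)) stop_param("line %d: expected >= 5 tab-separated fields", bad[1])
  chrom <- vapply(parts, `[[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  strand <- vapply(parts, `[[`, character(1), 3L)
  meth <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 4L)))
  unmeth <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 5L)))
  bad <- which(is.na(pos) | pos <= 0L)
  if (length(bad)) stop_param("line %d: invalid position", bad[1])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop_param("line %d: strand must be '+' or '-'", bad[1])
  bad <- which(is.na(meth) | is.na(unmeth) | meth < 0 | unmeth < 0 |
                 meth != floor(meth) | unmeth != floor(unmeth))
  if (length(bad)) stop_param("line %d: counts must be non-negative integers", bad[1])
  rec <- data.frame(chrom = chrom, pos = pos, strand = strand,
                    n_meth = as.integer(meth),
                    n_total = as.integer(meth + unmeth),
                    stringsAsFactors = FALSE)
  new_methylome(rec, sample_id, group)
}

#' Write a methylome as a cytosine report
#'
#' Records are written tab-separated in deterministic order (chromosome
#' lexicographic, then position): chrom, pos, strand, methylated count,
#' unmethylated count, context ("CG"). Round-trip stable with
#' \code{\link{read_cytosine_report}}.
#'
#' @param methylome A \code{methylome}.
#' @param path Output path.
#' @export
write_cytosine_report <- function(methylome, path) {
  m <- validate_methylome(methylome)
  r <- m$records[order(m$records$chrom, m$records$pos), , drop = FALSE]
  out <- sprintf("%s\t%d\t%s\t%d\t%d\tCG", r$chrom, r$pos, r$strand,
                 r$n_meth, r$n_total - r$n_meth)
  writeLines(out, path)
  invisible(path)
}

#' Filter CpGs by group-level coverage
#'
#' Builds the joint count matrix over all samples and keeps a CpG if and
#' only if, in each group, the coverage summed over that group's replicates
#' reaches \code{min_cov} (the default 10-read rule). With
#' \code{per_sample = TRUE} the stricter reading is applied instead: every
#' individual sample must reach \code{min_cov}.
#'
#' @param methylomes list of \code{methylome} objects covering exactly two
#'   groups.
#' @param min_cov Minimum coverage (default 10).
#' @param per_sample Apply the rule per sample instead of per group.
#' @return An object of class \code{meth_matrix}: list with \code{keys}
#'   (data.frame chrom, pos, strand), \code{meth} and \code{total} (CpG x
#'   sample integer matrices), \code{samples}, \code{groups} and the counts
#'   of retained/dropped sites.
#' @export
coverage_filter <- function(methylomes, min_cov = 10L, per_sample = FALSE) {
  if (min_cov < 1) stop_param("`min_cov` must be >= 1")
  if (inherits(methylomes, "meth_matrix")) {
    return(filter_matrix(methylomes, min_cov, per_sample))
  }
  stopifnot(is.list(methylomes), length(methylomes) >= 2L)
  groups <- vapply(methylomes, function(m) m$group, character(1))
  samples <- vapply(methylomes, function(m) m$sample_id, character(1))
  ug <- unique(groups)
  if (length(ug) != 2L || any(is.na(groups))) {
    stop_param("samples must carry exactly two known group labels (got: %s)",
               paste(unique(groups), collapse = ", "))
  }
  keys <- unique(do.call(rbind, lapply(methylomes, function(m) {
    m$records[, c("chrom", "pos", "strand")]
  })))
  keys <- keys[order(keys$chrom, keys$pos, keys$strand), , drop = FALSE]
  rownames(keys) <- NULL
  kid <- paste(keys$chrom, keys$pos, keys$strand)
  n <- nrow(keys)
  meth <- total <- matrix(0L, n, length(methylomes),
                          dimnames = list(NULL, samples))
  for (j in seq_along(methylomes)) {
    r <- methylomes[[j]]$records
    idx <- match(paste(r$chrom, r$pos, r$strand), kid)
    meth[idx, j] <- r$n_meth
    total[idx, j] <- r$n_total
  }
  mm <- structure(list(keys = keys, meth = meth, total = total,
                       samples = samples, groups = groups,
                       n_input = n, n_retained = n, n_dropped = 0L,
                       min_cov = NA_integer_, per_sample = per_sample),
                  class = "meth_matrix")
  filter_matrix(mm, min_cov, per_sample)
}

filter_matrix <- function(mm, min_cov, per_sample = FALSE) {
  keep_group <- function(g) {
    cols <- mm$groups == g
    if (per_sample) {
      apply(mm$total[, cols, drop = FALSE] >= min_cov, 1L, all)
    } else {
      rowSums(mm$total[, cols, drop = FALSE]) >= min_cov
    }
  }
  keep <- Reduce(`&`, lapply(unique(mm$groups), keep_group))
  out <- mm
  out$keys <- mm$keys[keep, , drop = FALSE]; rownames(out$keys) <- NULL
  out$meth <- mm$meth[keep, , drop = FALSE]
  out$total <- mm$total[keep, , drop = FALSE]
  out$n_input <- nrow(mm$keys)
  out$n_retained <- sum(keep)
  out$n_dropped <- sum(!keep)
  out$min_cov <- as.integer(min_cov)
  out$per_sample <- per_sample
  out
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf(paste0("<meth_matrix> %d CpG x %d samples (groups: %s); ",
                     "%d retained / %d dropped at min_cov = %s\n"),
              nrow(x$keys), length(x$samples),
              paste(unique(x$groups), collapse = " vs "),
              x$n_retained, x$n_dropped, x$min_cov))
  invisible(x)
}

#' Estimate bisulfite conversion efficiency from spike-in counts
#'
#' Pools converted and total read counts over all spike-in sites (per sample
#' if a \code{sample} column is present) and reports the converted fraction
#' together with a pass flag against a threshold.
#'
#' @param spikein data.frame with columns \code{converted} and \code{total}
#'   (and optionally \code{sample}).
#' @param threshold Pass threshold on efficiency (default 0.99).
#' @return data.frame with columns sample, converted, total, efficiency, pass.
#' @export
conversion_efficiency <- function(spikein, threshold = 0.99) {
  stopifnot(all(c("converted", "total") %in% names(spikein)))
  if (nrow(spikein) == 0L) stop_param("spike-in table is empty")
  if (any(spikein$total <= 0) || sum(spikein$total) == 0) {
    stop_param("spike-in depth must be positive at every site")
  }
  if (any(spikein$converted > spikein$total)) {
    stop_param("converted count exceeds total")
  }
  grp <- if ("sample" %in% names(spikein)) spikein$sample else "pooled"
  agg <- stats::aggregate(cbind(converted, total) ~ grp, data =
                            transform(spikein, grp = grp), FUN = sum)
  data.frame(sample = agg$grp, converted = agg$converted, total = agg$total,
             efficiency = agg$converted / agg$total,
             pass = agg$converted / agg$total >= threshold,
             stringsAsFactors = FALSE)
}

#' Global methylation summary
#'
#' Per-sample mean methylation (unweighted mean over CpGs of the per-CpG
#' fraction, the quantity a violin plot of per-CpG fractions displays),
#' group means, and the CD8 minus DN difference.
#'
#' @param mm A \code{meth_matrix}.
#' @param reference,case Group labels for the difference
#'   (default \code{"CD8"} - \code{"DN"}).
#' @return list with \code{per_sample} (data.frame sample, group,
#'   mean_methylation), \code{group_means} (named numeric) and
#'   \code{difference} (reference mean minus case mean).
#' @export
global_methylation_summary <- function(mm, reference = "CD8", case = "DN") {
  stopifnot(inherits(mm, "meth_matrix"))
  if (nrow(mm$keys) == 0L) stop_param("empty methylation matrix")
  frac <- mm$meth / mm$total
  per_sample <- colMeans(frac, na.rm = TRUE)  # NA where a sample has 0 reads
  ps <- data.frame(sample = mm$samples, group = mm$groups,
                   mean_methylation = unname(per_sample),
                   stringsAsFactors = FALSE)
  gm <- tapply(ps$mean_methylation, ps$group, mean)
  diff <- if (all(c(reference, case) %in% names(gm))) {
    unname(gm[reference] - gm[case])
  } else NA_real_
  list(per_sample = ps, group_means = gm, difference = diff)
}
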