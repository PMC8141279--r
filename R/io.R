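# Plain-text writers/readers for the small interval and table formats the
# pipeline exchanges. All interval files are 0-based half-open.

#' Write a BED file
#' @param x data.frame with chrom, start, end and optionally name, score,
#'   strand; missing BED6 columns are filled (".", 0, "+").
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, what = "BED interval")
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = x$name %||% ".", score = x$score %||% 0,
                    strand = x$strand %||% "+", stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#' @param path File path.
#' @return data.frame with chrom, start, end (+ name, score, strand when
#'   present).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4L) names(x)[4] <- "name"
  if (ncol(x) >= 5L) names(x)[5] <- "score"
  if (ncol(x) >= 6L) names(x)[6] <- "strand"
  validate_intervals(x, what = "BED interval")
  x
}

#' Write a bedGraph track
#' @param track data.frame with chrom, start, end, value.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  validate_intervals(track, what = "bedGraph interval")
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#' @param path File path.
#' @return data.frame with chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "value"))
  validate_intervals(x, what = "bedGraph interval")
  if (any(!is.finite(x$value))) stop_param("non-finite value in bedGraph")
  x
}

#' Write a tab-separated table with header
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table with header
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
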