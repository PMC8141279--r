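#' Annotate loci to the nearest transcription start site
#'
#' For each locus, finds the TSS on the same chromosome minimising the
#' absolute base-pair distance (strand-ignored point distance). Ties are
#' broken by the lexicographically smallest gene id. Loci on chromosomes
#' without any TSS are returned unannotated (NA gene) and counted.
#'
#' @param dml data.frame with columns \code{chrom}, \code{pos} (1-based);
#'   typically significant DML, but any locus table works.
#' @param tss_table data.frame with columns \code{gene}, \code{chrom},
#'   \code{tss} (1-based); unique gene ids, one TSS per gene.
#' @return The input plus columns \code{gene} and \code{distance}
#'   (signed, pos - tss).
#' @export
nearest_tss <- function(dml, tss_table) {
  if (is.null(tss_table) || nrow(tss_table) == 0L) stop_param("TSS table is empty")
  if (anyDuplicated(tss_table$gene)) stop_param("TSS table has duplicate gene ids")
  out <- as.data.frame(dml)
  out$gene <- NA_character_
  out$distance <- NA_integer_
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    t <- tss_table[tss_table$chrom == ch, , drop = FALSE]
    if (nrow(t) == 0L) next
    # order by position, then gene id, so that among equal positions the
    # smallest gene id is scanned first
    t <- t[order(t$tss, t$gene), , drop = FALSE]
    pos <- out$pos[idx]
    j <- findInterval(pos, t$tss)            # last tss <= pos
    lo <- pmax(j, 1L); hi <- pmin(j + 1L, nrow(t))
    d_lo <- abs(pos - t$tss[lo]); d_lo[j < 1L] <- Inf
    d_hi <- abs(pos - t$tss[hi]); d_hi[j + 1L > nrow(t)] <- Inf
    # tie at equal distance: prefer the smaller gene id
    pick_lo <- d_lo < d_hi |
      (d_lo == d_hi & t$gene[lo] <= t$gene[hi])
    best <- ifelse(pick_lo, lo, hi)
    # among duplicated tss positions, the scan above sees only one row per
    # position; resolve exact-position ties on gene id explicitly
    for (k in seq_along(idx)) {
      bt <- t$tss[best[k]]
      cand <- which(t$tss == bt)
      if (length(cand) > 1L) best[k] <- cand[order(t$gene[cand])][1L]
    }
    out$gene[idx] <- t$gene[best]
    out$distance[idx] <- pos - t$tss[best]
  }
  n_un <- sum(is.na(out$gene))
  if (n_un > 0) {
    message(sprintf("nearest_tss: %d locus/loci on chromosomes without a TSS left unannotated", n_un))
  }
  out
}

#' Integrate annotated DML with differential expression
#'
#' Joins TSS-annotated DML with a gene-level expression table and reports
#' the overlap structure the methylation/expression meta-analysis uses:
#' how many upregulated genes carry at least one hypomethylated DML, how
#' many DML map to significantly changed genes (and how many of those are
#' hypo), and the quadrant counts of (methylation change, expression
#' change) pairs.
#'
#' @param annotated_dml Output of \code{\link{nearest_tss}} with columns
#'   \code{delta} and \code{direction} present (i.e. annotated significant
#'   DML).
#' @param expression data.frame with columns \code{gene}, \code{lfc},
#'   \code{pvalue}, \code{upregulated}.
#' @return list with \code{joined} (per-DML table with gene expression
#'   columns), \code{n_up_genes_with_hypo_dml}, \code{n_dml_at_up_genes},
#'   \code{n_hypo_dml_at_up_genes}, and \code{quadrants} (named counts:
#'   hypo_up, hypo_down, hyper_up, hyper_down over DML with nonzero lfc).
#' @export
integrate_expression <- function(annotated_dml, expression) {
  if (is.null(expression) || nrow(expression) == 0L) {
    stop_param("expression table is empty")
  }
  stopifnot(all(c("gene", "lfc", "pvalue", "upregulated") %in% names(expression)))
  j <- match(annotated_dml$gene, expression$gene)
  joined <- annotated_dml
  joined$lfc <- expression$lfc[j]
  joined$expr_pvalue <- expression$pvalue[j]
  joined$upregulated <- expression$upregulated[j]
  at_up <- !is.na(joined$upregulated) & joined$upregulated
  hypo <- joined$delta < 0
  quad <- c(
    hypo_up = sum(hypo & !is.na(joined$lfc) & joined$lfc > 0),
    hypo_down = sum(hypo & !is.na(joined$lfc) & joined$lfc < 0),
    hyper_up = sum(!hypo & !is.na(joined$lfc) & joined$lfc > 0),
    hyper_down = sum(!hypo & !is.na(joined$lfc) & joined$lfc < 0)
  )
  list(joined = joined,
       n_up_genes_with_hypo_dml = length(unique(joined$gene[at_up & hypo])),
       n_dml_at_up_genes = sum(at_up),
       n_hypo_dml_at_up_genes = sum(at_up & hypo),
       quadrants = quad)
}

#' Rank genes by their burden of demethylated DML
#'
#' Counts, per gene, the hypomethylated DML annotated to it and returns
#' genes in descending count order (ties broken by gene id). Restricted to
#' upregulated genes when the joined table carries the flag and
#' \code{upregulated_only = TRUE}.
#'
#' @param joined The \code{joined} table from
#'   \code{\link{integrate_expression}} (or any table with \code{gene} and
#'   \code{delta}).
#' @param upregulated_only Restrict to genes flagged upregulated
#'   (default TRUE when the column exists).
#' @return data.frame with columns gene, n_hypo_dml, rank.
#' @export
rank_genes_by_dml <- function(joined, upregulated_only = TRUE) {
  tab <- joined
  if (upregulated_only && "upregulated" %in% names(tab)) {
    tab <- tab[!is.na(tab$upregulated) & tab$upregulated, , drop = FALSE]
  }
  tab <- tab[!is.na(tab$gene) & tab$delta < 0, , drop = FALSE]
  if (nrow(tab) == 0L) {
    return(data.frame(gene = character(0), n_hypo_dml = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  cnt <- table(tab$gene)
  out <- data.frame(gene = names(cnt), n_hypo_dml = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_hypo_dml, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
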