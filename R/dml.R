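#' Estimate beta-binomial dispersions with empirical-Bayes shrinkage
#'
#' Per CpG, a method-of-moments dispersion is computed from the replicate
#' methylation proportions, pooling squared deviations from the group means
#' over both groups:
#' \deqn{\hat\phi_i = \frac{\sum_{g,r} (\hat p_{gr} - \hat\mu_g)^2 -
#'   \sum_{g,r} \hat\mu_g(1-\hat\mu_g)/N_{gr}}
#'   {\sum_{g,r} \hat\mu_g(1-\hat\mu_g)(N_{gr}-1)/N_{gr}}}
#' clamped at zero. Raw log-dispersions are then shrunk towards their
#' empirical prior: with \eqn{(m_0, r_0^2)} the mean and variance of
#' \eqn{\log\hat\phi} over CpGs with finite positive \eqn{\hat\phi}, the
#' shrunk value is \eqn{\tilde\phi_i = \exp(w_i \log\hat\phi_i +
#' (1-w_i) m_0)} with \eqn{w_i = r_0^2 / (r_0^2 + s_i^2)} and
#' \eqn{s_i^2 = 2/(n_i - 1)}, \eqn{n_i} the number of replicates (both
#' groups) with nonzero coverage at CpG \eqn{i}. CpGs with undefined or
#' non-positive \eqn{\hat\phi} receive \eqn{\exp(m_0)}. When no CpG yields a
#' usable raw estimate the weakly informative fallback prior
#' \eqn{(m_0, r_0^2) = (\log 0.01, 1)} is used.
#'
#' @param mm A \code{meth_matrix} from \code{\link{coverage_filter}}.
#' @return Object of class \code{dispersion_estimate}: list with
#'   \code{phi_raw}, \code{phi_shrunk} (numeric per CpG), \code{m0},
#'   \code{r02}.
#' @export
estimate_dispersions <- function(mm) {
  stopifnot(inherits(mm, "meth_matrix"))
  n <- nrow(mm$keys)
  if (n < 1L) stop_param("no CpGs to estimate dispersions from")
  ss <- a <- b <- numeric(n)
  for (g in unique(mm$groups)) {
    cols <- mm$groups == g
    X <- mm$meth[, cols, drop = FALSE]
    N <- mm$total[, cols, drop = FALSE]
    mu <- rowSums(X) / rowSums(N)
    P <- X / N                       # NaN where N == 0; excluded below
    dev2 <- (P - mu)^2
    v <- mu * (1 - mu)
    ss <- ss + rowSums(dev2 * (N > 0), na.rm = TRUE)
    a <- a + rowSums((v / N) * (N > 0), na.rm = TRUE)
    b <- b + rowSums(v * (N - 1) / N * (N > 0), na.rm = TRUE)
  }
  phi_raw <- ifelse(b > 0, (ss - a) / b, NA_real_)
  phi_raw <- pmax(phi_raw, 0)
  usable <- is.finite(phi_raw) & phi_raw > 0
  if (sum(usable) >= 2L) {
    lp <- log(phi_raw[usable])
    m0 <- mean(lp); r02 <- stats::var(lp)
    if (!is.finite(r02) || r02 <= 0) { m0 <- log(0.01); r02 <- 1 }
  } else {
    m0 <- log(0.01); r02 <- 1
  }
  n_eff <- rowSums(mm$total > 0)
  s2 <- 2 / pmax(n_eff - 1, 1)
  w <- r02 / (r02 + s2)
  phi_shrunk <- ifelse(usable, exp(w * log(phi_raw) + (1 - w) * m0), exp(m0))
  structure(list(phi_raw = phi_raw, phi_shrunk = phi_shrunk,
                 m0 = m0, r02 = r02),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf(paste0("<dispersion_estimate> %d CpG; prior m0 = %.3f ",
                     "(phi %.4g), r0^2 = %.3f; mean shrunk phi = %.4g\n"),
              length(x$phi_shrunk), x$m0, exp(x$m0), x$r02,
              mean(x$phi_shrunk)))
  invisible(x)
}

#' Beta-binomial Wald test for a two-group methylation difference
#'
#' For each CpG, group means are pooled-count estimates
#' \eqn{\hat\mu_g = \sum_r X_{gr} / \sum_r N_{gr}} with beta-binomial
#' variance \eqn{\widehat{Var}_g = \hat\mu_g(1-\hat\mu_g)
#' \sum_r N_{gr}(1 + (N_{gr}-1)\tilde\phi_i) / (\sum_r N_{gr})^2}. The Wald
#' statistic is \eqn{t = \Delta / \sqrt{\widehat{Var}_1 + \widehat{Var}_2}}
#' with \eqn{\Delta = \hat\mu_{case} - \hat\mu_{ref}}, referred to the
#' standard normal (two-sided). When both group means are exactly 0 or 1 the
#' variance collapses; it is then recomputed with \eqn{\hat\mu_g} replaced
#' by \eqn{(\sum X + 0.5)/(\sum N + 1)}, which keeps \eqn{t} finite while
#' preserving the direction. \eqn{\Delta = 0} yields \eqn{t = 0, p = 1}.
#'
#' @param mm A \code{meth_matrix}.
#' @param dispersions A \code{dispersion_estimate} for the same matrix.
#' @param reference,case Group labels; \code{delta} is case minus reference
#'   (default DN minus CD8, so demethylation in DN gives negative delta).
#' @return data.frame with columns chrom, pos, strand, mu_ref, mu_case,
#'   delta, stat, pvalue; attribute \code{groups} records the label order.
#' @export
wald_test <- function(mm, dispersions, reference = "CD8", case = "DN") {
  stopifnot(inherits(mm, "meth_matrix"),
            inherits(dispersions, "dispersion_estimate"))
  if (length(dispersions$phi_shrunk) != nrow(mm$keys)) {
    stop_param("dispersion vector does not match the matrix")
  }
  if (!all(c(reference, case) %in% mm$groups)) {
    stop_param("matrix lacks group '%s' or '%s'", reference, case)
  }
  phi <- dispersions$phi_shrunk
  stats_g <- function(g) {
    cols <- mm$groups == g
    X <- mm$meth[, cols, drop = FALSE]
    N <- mm$total[, cols, drop = FALSE]
    sn <- rowSums(N)
    mu <- rowSums(X) / sn
    vw <- rowSums(N * (1 + (N - 1) * phi)) / sn^2
    list(mu = mu, vw = vw, sx = rowSums(X), sn = sn)
  }
  r <- stats_g(reference); c_ <- stats_g(case)
  v_ref <- r$mu * (1 - r$mu) * r$vw
  v_case <- c_$mu * (1 - c_$mu) * c_$vw
  vt <- v_ref + v_case
  deg <- vt <= 0
  if (any(deg)) {
    mu_r <- (r$sx + 0.5) / (r$sn + 1)
    mu_c <- (c_$sx + 0.5) / (c_$sn + 1)
    vt[deg] <- (mu_r * (1 - mu_r) * r$vw + mu_c * (1 - mu_c) * c_$vw)[deg]
  }
  delta <- c_$mu - r$mu
  stat <- ifelse(delta == 0, 0, delta / sqrt(vt))
  pvalue <- 2 * stats::pnorm(-abs(stat))
  pvalue <- pmin(pmax(pvalue, .Machine$double.xmin), 1)
  out <- data.frame(chrom = mm$keys$chrom, pos = mm$keys$pos,
                    strand = mm$keys$strand, mu_ref = r$mu, mu_case = c_$mu,
                    delta = delta, stat = stat, pvalue = pvalue,
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- c(reference = reference, case = case)
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment with monotonicity enforcement, order-preserving with
#' the input.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of FDR-adjusted values, same order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues))) stop_param("NA/NaN p-value in input")
  if (any(pvalues <= 0 | pvalues > 1)) stop_param("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially methylated loci
#'
#' A CpG is significant iff FDR < \code{fdr_threshold} and |delta| >
#' \code{min_delta}, both strict, the 20 percent / FDR 0.05 rule by default.
#' The full table (including non-significant CpGs) is kept; direction is
#' "hypo" for negative delta (demethylated in the case group).
#'
#' @param test_results Output of \code{\link{wald_test}}.
#' @param fdr_threshold FDR cutoff in (0, 1), default 0.05.
#' @param min_delta Minimum absolute methylation difference in (0, 1),
#'   default 0.20.
#' @return Object of class \code{dml_result}: the annotated table plus a
#'   direction summary, with print, summary, plot and as.data.frame methods.
#' @export
call_dml <- function(test_results, fdr_threshold = 0.05, min_delta = 0.20) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop_param("`fdr_threshold` must be in (0, 1)")
  }
  if (min_delta <= 0 || min_delta >= 1) stop_param("`min_delta` must be in (0, 1)")
  tab <- as.data.frame(test_results)
  tab$fdr <- bh_fdr(tab$pvalue)
  tab$direction <- ifelse(tab$delta < 0, "hypo",
                          ifelse(tab$delta > 0, "hyper", "none"))
  tab$significant <- tab$fdr < fdr_threshold & abs(tab$delta) > min_delta
  sig <- tab[tab$significant, , drop = FALSE]
  n_hypo <- sum(sig$direction == "hypo")
  n_hyper <- sum(sig$direction == "hyper")
  structure(list(
    table = tab,
    groups = attr(test_results, "groups"),
    fdr_threshold = fdr_threshold,
    min_delta = min_delta,
    summary = list(n_tested = nrow(tab), n_significant = nrow(sig),
                   n_hypo = n_hypo, n_hyper = n_hyper,
                   hypo_fraction = if (nrow(sig)) n_hypo / nrow(sig) else NA_real_)
  ), class = "dml_result")
}

#' @export
print.dml_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<dml_result> %d CpG tested; %d significant (FDR < %g, |delta| > %g)\n",
              s$n_tested, s$n_significant, x$fdr_threshold, x$min_delta))
  if (s$n_significant > 0) {
    cat(sprintf("  hypo: %d (%.1f%%)   hyper: %d (%.1f%%)\n",
                s$n_hypo, 100 * s$hypo_fraction,
                s$n_hyper, 100 * (1 - s$hypo_fraction)))
  }
  invisible(x)
}

#' @export
summary.dml_result <- function(object, ...) object$summary

#' @export
as.data.frame.dml_result <- function(x, ...) x$table

#' Volcano plot of a DML result
#' @param x A \code{dml_result}.
#' @param ... Passed to \code{plot}.
#' @export
plot.dml_result <- function(x, ...) {
  v <- volcano_table(x)
  col <- ifelse(x$table$significant,
                ifelse(x$table$delta < 0, "#2166AC", "#B2182B"), "grey60")
  graphics::plot(v$delta, v$neglog10_fdr, pch = 16, cex = 0.4, col = col,
                 xlab = "methylation difference (case - reference)",
                 ylab = expression(-log[10] ~ FDR), ...)
  graphics::abline(v = c(-x$min_delta, x$min_delta), lty = 3)
  graphics::abline(h = -log10(x$fdr_threshold), lty = 3)
  invisible(x)
}

#' Significant loci of a DML result
#' @param x A \code{dml_result}.
#' @return data.frame of significant rows.
#' @export
significant_dml <- function(x) {
  stopifnot(inherits(x, "dml_result"))
  x$table[x$table$significant, , drop = FALSE]
}

#' Volcano table: (delta, -log10 FDR) pairs
#' @param x A \code{dml_result} or a data.frame with delta and fdr columns.
#' @return data.frame with columns delta, neglog10_fdr.
#' @export
volcano_table <- function(x) {
  tab <- if (inherits(x, "dml_result")) x$table else x
  data.frame(delta = tab$delta, neglog10_fdr = -log10(tab$fdr))
}

#' Per-window minimum-p significance profile
#'
#' Tiles each chromosome in fixed windows and reports, per non-empty
#' window, the minimum p-value of the CpGs inside, as a bedGraph-ready
#' table (value = -log10 of the window minimum p). Multiple resolutions are
#' obtained by calling with different \code{window_bp}.
#'
#' @param test_results Output of \code{\link{wald_test}} (or the table of a
#'   \code{dml_result}).
#' @param window_bp Window size in bp (>= 1).
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   min_p, value (-log10 min_p).
#' @export
chromosome_significance_profile <- function(test_results, window_bp) {
  if (window_bp < 1) stop_param("`window_bp` must be >= 1")
  tab <- if (inherits(test_results, "dml_result")) test_results$table else test_results
  window_bp <- as.integer(window_bp)
  rows <- lapply(split(tab, tab$chrom), function(d) {
    win <- (d$pos - 1L) %/% window_bp
    mp <- tapply(d$pvalue, win, min)
    w <- as.integer(names(mp))
    data.frame(chrom = d$chrom[1], start = w * window_bp,
               end = (w + 1L) * window_bp, min_p = as.numeric(mp),
               value = -log10(as.numeric(mp)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
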