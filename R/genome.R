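#' Build a synthetic genome model
#'
#' Creates a small stand-in genome: one or more chromosomes of fixed length,
#' a sorted set of CpG positions per chromosome, and (optionally) a random
#' nucleotide sequence carrying a \code{"CG"} dinucleotide at every CpG
#' position. The model is the coordinate system every other simulator and
#' every interval operation in the package works against.
#'
#' @param n_chroms Number of chromosomes (named \code{chr1}, \code{chr2}, ...).
#' @param chrom_length_bp Length of every chromosome in bp (>= 10000).
#' @param cpg_density Expected fraction of base pairs that start a CpG,
#'   in (0, 0.1]. The realised CpG count per chromosome is binomial.
#' @param seed Integer seed; the model is deterministic given it.
#' @param with_sequence If \code{TRUE} (default) a random A/C/G/T sequence is
#'   generated per chromosome and a CG dinucleotide written at each CpG site.
#' @return An object of class \code{genome_model}: a list with
#'   \code{chrom_names}, \code{chrom_lengths} (named integer vector),
#'   \code{cpg_positions} (named list of sorted 1-based positions) and
#'   \code{sequence} (named character vector or \code{NULL}).
#' @examples
#' gm <- build_genome(1, 50000, 0.01, seed = 1)
#' length(gm$cpg_positions$chr1)
#' @export
build_genome <- function(n_chroms = 1L, chrom_length_bp = 1e6, cpg_density = 0.01,
                         seed = 1L, with_sequence = TRUE) {
  if (!is.numeric(n_chroms) || n_chroms < 1) stop_param("`n_chroms` must be >= 1")
  if (!is.numeric(chrom_length_bp) || chrom_length_bp < 10000) {
    stop_param("`chrom_length_bp` must be >= 10000")
  }
  if (!is.numeric(cpg_density) || cpg_density <= 0 || cpg_density > 0.1) {
    stop_param("`cpg_density` must lie in (0, 0.1]")
  }
  n_chroms <- as.integer(n_chroms)
  L <- as.integer(chrom_length_bp)
  chroms <- paste0("chr", seq_len(n_chroms))
  with_seed(seed, {
    cpg <- lapply(chroms, function(ch) {
      n <- rbinom(1L, L - 1L, cpg_density)
      p <- sort(sample.int(L - 1L, n))
      # adjacent starts would make the CG dinucleotides overlap; keep the
      # first of any adjacent pair
      while (length(p) > 1L && any(diff(p) < 2L)) {
        p <- p[c(TRUE, diff(p) >= 2L)]
      }
      p
    })
    names(cpg) <- chroms
    seqs <- NULL
    if (with_sequence) {
      seqs <- vapply(chroms, function(ch) {
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        s[cpg[[ch]]] <- "C"
        s[cpg[[ch]] + 1L] <- "G"
        paste(s, collapse = "")
      }, character(1))
    }
    gm <- structure(list(
      chrom_names = chroms,
      chrom_lengths = stats::setNames(rep(L, n_chroms), chroms),
      cpg_positions = cpg,
      sequence = seqs
    ), class = "genome_model")
    validate_genome(gm)
    gm
  })
}

validate_genome <- function(gm) {
  stopifnot(inherits(gm, "genome_model"))
  for (ch in gm$chrom_names) {
    pos <- gm$cpg_positions[[ch]]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop_param("CpG positions on %s are not strictly increasing", ch)
    }
    if (length(pos) && (min(pos) < 1L || max(pos) > gm$chrom_lengths[[ch]] - 1L)) {
      stop_param("CpG position out of bounds on %s", ch)
    }
    if (!is.null(gm$sequence)) {
      dinuc <- substring(gm$sequence[[ch]], pos, pos + 1L)
      if (length(pos) && any(dinuc != "CG")) {
        stop_param("sequence of %s lacks CG at a declared CpG position", ch)
      }
    }
  }
  invisible(gm)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), %s bp total, %d CpG sites%s\n",
              length(x$chrom_names),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ","),
              sum(lengths(x$cpg_positions)),
              if (is.null(x$sequence)) ", no sequence" else ""))
  invisible(x)
}

reverse_complement <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Plant motif instances near anchor positions
#'
#' Writes a motif consensus into the genome sequence at a uniform offset
#' within \code{+/- window} bp of each anchor, with probability
#' \code{planting_rate} per anchor. A planting site is re-drawn (up to 25
#' attempts) if it would overwrite a declared CpG dinucleotide, so the
#' methylome's coordinates stay valid; anchors whose window falls off the
#' chromosome end, or for which no CpG-free site is found, are skipped and
#' logged.
#'
#' @param genome A \code{genome_model} with sequence.
#' @param anchors data.frame with columns \code{chrom}, \code{pos} (1-based).
#' @param consensus Motif string to write (A/C/G/T), e.g. \code{"TGACTCA"}.
#' @param planting_rate Probability of planting per anchor, in [0, 1].
#' @param window Half-width of the placement window around the anchor (bp).
#' @param seed Integer seed.
#' @return list with \code{genome} (modified model) and \code{log}
#'   (data.frame: chrom, anchor_pos, planted, start; start is 1-based, NA if
#'   not planted).
#' @export
plant_motifs <- function(genome, anchors, consensus, planting_rate = 1,
                         window = 200L, seed = 1L) {
  validate_genome(genome)
  if (is.null(genome$sequence)) stop_param("genome has no sequence to plant into")
  if (planting_rate < 0 || planting_rate > 1) stop_param("`planting_rate` must be in [0, 1]")
  consensus <- toupper(consensus)
  if (!grepl("^[ACGT]+$", consensus)) stop_param("consensus must be A/C/G/T only")
  len <- nchar(consensus)
  if (len > 2L * window + 1L) stop_param("consensus longer than the placement window")
  seqs <- as.list(genome$sequence)
  log_rows <- vector("list", nrow(anchors))
  with_seed(seed, {
    for (i in seq_len(nrow(anchors))) {
      ch <- as.character(anchors$chrom[i]); pos <- as.integer(anchors$pos[i])
      L <- genome$chrom_lengths[[ch]]
      planted <- FALSE; start <- NA_integer_
      if (pos - window < 1L || pos + window > L) {
        # window off chromosome end: skip, but keep the RNG stream aligned
        runif(1)
      } else if (runif(1) < planting_rate) {
        cpg <- genome$cpg_positions[[ch]]
        for (try in seq_len(25L)) {
          s <- pos + sample.int(2L * window + 1L, 1L) - window - 1L
          s <- max(1L, min(s, L - len + 1L))
          # site must not cover any base of a declared CpG (pos or pos + 1)
          hit <- any(cpg >= s - 1L & cpg <= s + len - 1L)
          if (!hit) { start <- s; planted <- TRUE; break }
        }
        if (planted) {
          substr(seqs[[ch]], start, start + len - 1L) <- consensus
        }
      }
      log_rows[[i]] <- data.frame(chrom = ch, anchor_pos = pos,
                                  planted = planted, start = start,
                                  stringsAsFactors = FALSE)
    }
  })
  genome$sequence <- unlist(seqs)[genome$chrom_names]
  validate_genome(genome)
  list(genome = genome, log = do.call(rbind, log_rows))
}

#' Write a genome model's sequence as FASTA
#' @param genome A \code{genome_model} with sequence.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @export
write_genome_fasta <- function(genome, path, width = 80L) {
  validate_genome(genome)
  if (is.null(genome$sequence)) stop_param("genome has no sequence")
  con <- file(path, "w"); on.exit(close(con))
  for (ch in genome$chrom_names) {
    writeLines(paste0(">", ch), con)
    s <- genome$sequence[[ch]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
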