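# k-mer counting, enrichment ratios and Z-score significance.
#
# Overlapping k-mer occurrences are counted over the searched region of
# every read; a read of length lambda contributes lambda - k + 1 windows.
# Enrichment of a k-mer is its frequency in the protein-bound sample
# divided by its frequency in the input pool, and significance is judged
# against the 99.9th percentile of the Z-score distribution.

#' Count overlapping k-mers in a sample
#'
#' @param sample a \code{\link{sequencing_sample}}.
#' @param k motif length (nt). Default 10, the maximum effective motif
#'   size for de novo discovery at typical sequencing depth.
#' @param region either \code{"full"} or an integer pair
#'   \code{c(start, end)} (1-based, inclusive) restricting the searched
#'   window of each read.
#' @return an object of class \code{KmerCountTable}: list with \code{k},
#'   \code{counts} (named integer vector over all 4^k k-mers) and
#'   \code{total_positions}.
#' @export
count_kmers <- function(sample, k = 10L, region = "full") {
  stopifnot(inherits(sample, "SequencingSample"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k != round(k)) {
    stop("'k' must be a positive integer")
  }
  k <- as.integer(k)
  seqs <- sample$inserts
  if (!identical(region, "full")) {
    stopifnot(is.numeric(region), length(region) == 2L)
    if (length(seqs) && (region[1] < 1L || region[2] > nchar(seqs[1]) ||
                         region[1] > region[2])) {
      stop("'region' outside read bounds")
    }
    seqs <- substr(seqs, region[1], region[2])
  }
  if (length(seqs) && k > min(nchar(seqs))) {
    stop("'k' exceeds the searched region length")
  }
  if (!length(seqs)) {
    counts <- setNames(integer(0), character(0))
    return(structure(list(k = k, counts = counts, total_positions = 0),
                     class = "KmerCountTable"))
  }
  x <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(x, width = k, step = 1L,
                                                 simplify.as = "collapsed")
  structure(list(k = k, counts = counts,
                 total_positions = sum(nchar(seqs) - k + 1L)),
            class = "KmerCountTable")
}

#' k-mer frequencies from a count table
#'
#' @param table a \code{KmerCountTable}.
#' @return named numeric vector \code{counts / total_positions}.
#' @export
kmer_frequencies <- function(table) {
  stopifnot(inherits(table, "KmerCountTable"))
  if (table$total_positions == 0) return(table$counts * NA_real_)
  table$counts / table$total_positions
}

#' Enrichment ratios and Z-scores of bound versus pool k-mers
#'
#' Enrichment R(m) is the frequency of k-mer m in the bound sample divided
#' by its frequency in the pool; k-mers absent from the pool are excluded
#' (division by zero is not supported). Z-scores are computed over all
#' k-mers with a defined ratio, and the significance threshold is the
#' 99.9th percentile of the Z distribution (linear-interpolation empirical
#' percentile).
#'
#' @param bound,pool \code{KmerCountTable}s with equal \code{k}.
#' @param percentile significance percentile for the Z threshold
#'   (default 0.999).
#' @return an object of class \code{EnrichmentTable}: list with \code{k},
#'   \code{enrichment}, \code{mean_R}, \code{sd_R}, \code{z},
#'   \code{z_threshold}, \code{n_excluded} (pool-absent k-mers) and
#'   \code{degenerate} (TRUE when all enrichments are equal).
#' @export
enrichment_table <- function(bound, pool, percentile = 0.999) {
  stopifnot(inherits(bound, "KmerCountTable"), inherits(pool, "KmerCountTable"))
  if (bound$k != pool$k) stop("bound and pool tables must share 'k'")
  fp <- kmer_frequencies(pool)
  fb <- kmer_frequencies(bound)
  defined <- !is.na(fp) & fp > 0
  n_excluded <- sum(!defined)
  common <- names(fp)[defined]
  R <- fb[common] / fp[common]
  Rbar <- mean(R)
  S <- sd(R)
  degenerate <- !is.finite(S) || S == 0
  if (degenerate) {
    warning("degenerate enrichment table: all enrichment values are equal")
    z <- setNames(rep(0, length(R)), names(R))
    thr <- Inf   # nothing is significant
  } else {
    z <- (R - Rbar) / S
    thr <- unname(quantile(z, percentile, names = FALSE, type = 7))
  }
  structure(list(k = bound$k, enrichment = R, mean_R = Rbar, sd_R = S,
                 z = z, z_threshold = thr, n_excluded = n_excluded,
                 degenerate = degenerate),
            class = "EnrichmentTable")
}

#' Is a motif significantly enriched?
#'
#' TRUE iff the motif's Z-score is at or above the table's percentile
#' threshold. In a degenerate table (all enrichments equal) no motif is
#' significant.
#'
#' @param table an \code{EnrichmentTable}.
#' @param motif k-mer present in the table.
#' @return logical scalar.
#' @export
zscore_significant <- function(table, motif) {
  stopifnot(inherits(table, "EnrichmentTable"))
  motif <- as_dna(motif)
  if (!motif %in% names(table$z)) stop("motif not present in table: ", motif)
  if (table$degenerate) return(FALSE)
  unname(table$z[motif] >= table$z_threshold)
}

#' Write an enrichment table as TSV
#'
#' @param table an \code{EnrichmentTable}.
#' @param bound,pool the \code{KmerCountTable}s the table was built from.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_enrichment_tsv <- function(table, bound, pool, path) {
  m <- names(table$enrichment)
  df <- data.frame(
    kmer = m,
    count_bound = as.numeric(bound$counts[m]),
    count_pool = as.numeric(pool$counts[m]),
    freq_bound = as.numeric(kmer_frequencies(bound)[m]),
    freq_pool = as.numeric(kmer_frequencies(pool)[m]),
    enrichment = as.numeric(table$enrichment),
    zscore = as.numeric(table$z),
    significant = as.numeric(table$z) >= table$z_threshold & !table$degenerate)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
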