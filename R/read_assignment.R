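# Assignment of reads to site categories and pool composition.
#
# A read is assigned to a site category when it contains a single binding
# motif locus. Because site motifs are nested (the 8mer contains the
# 7mer-m8, 7mer-A1 and 6mer), co-located nested occurrences collapse to
# the most specific (longest) motif; reads with two or more distinct loci
# (disjoint or partially overlapping) are excluded in exclusive mode or
# fractionally split in fractional mode. Reads with no motif are no-site.

#' Assign reads of one sample to site categories
#'
#' @param sample a \code{\link{sequencing_sample}}.
#' @param motifs named character vector, label -> motif (RNA or DNA); all
#'   motif strings must be distinct.
#' @param region \code{NULL} to search the full read, or an integer pair
#'   \code{c(start, end)} restricting the searchable interval (e.g. the
#'   random region plus 4 accessible flanking nucleotides when blocker
#'   oligonucleotides were annealed).
#' @param mode \code{"exclusive"} (multi-locus reads excluded, integer
#'   counts) or \code{"fractional"} (multi-locus reads contribute 1/L to
#'   each of their L loci).
#' @return named numeric vector of counts over \code{c(names(motifs),
#'   "no-site")}, with attributes \code{excluded} (reads dropped in
#'   exclusive mode) and \code{total}.
#' @export
assign_reads <- function(sample, motifs, region = NULL,
                         mode = c("exclusive", "fractional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "SequencingSample"), length(motifs) >= 1)
  dna <- as_dna(motifs)
  if (anyDuplicated(dna)) {
    stop("duplicate motif strings must be merged upstream: ",
         paste(unique(dna[duplicated(dna)]), collapse = ", "))
  }
  labels <- names(motifs)
  if (is.null(labels) || any(labels == "")) stop("motifs must be named")
  seqs <- sample$inserts
  if (!is.null(region)) {
    stopifnot(is.numeric(region), length(region) == 2L)
    if (length(seqs) && (region[1] < 1 || region[2] > nchar(seqs[1]))) {
      stop("'region' outside read bounds")
    }
    seqs <- substr(seqs, region[1], region[2])
  }
  counts <- setNames(numeric(length(labels) + 1L), c(labels, "no-site"))
  excluded <- 0
  n <- length(seqs)
  if (n == 0L) {
    attr(counts, "excluded") <- 0; attr(counts, "total") <- 0
    attr(counts, "mode") <- mode
    return(counts)
  }
  # all occurrence loci of every motif, per read
  widths <- nchar(dna)
  hit_list <- lapply(seq_along(dna), function(i) {
    g <- gregexpr(dna[i], seqs, fixed = TRUE)
    lapply(g, function(p) if (p[1] == -1L) integer(0) else as.integer(p))
  })
  for (r in seq_len(n)) {
    starts <- integer(0); ends <- integer(0); lab <- integer(0)
    for (i in seq_along(dna)) {
      p <- hit_list[[i]][[r]]
      if (length(p)) {
        starts <- c(starts, p); ends <- c(ends, p + widths[i] - 1L)
        lab <- c(lab, rep(i, length(p)))
      }
    }
    if (!length(starts)) {
      counts["no-site"] <- counts["no-site"] + 1
      next
    }
    # collapse occurrences nested within a longer occurrence
    keep <- rep(TRUE, length(starts))
    for (a in seq_along(starts)) {
      contained <- starts >= starts[a] & ends <= ends[a] &
        (ends - starts) < (ends[a] - starts[a])
      keep[contained] <- FALSE
    }
    loci <- which(keep)
    if (length(loci) == 1L) {
      counts[lab[loci]] <- counts[lab[loci]] + 1
    } else if (mode == "exclusive") {
      excluded <- excluded + 1
    } else {
      w <- 1 / length(loci)
      for (a in loci) counts[lab[a]] <- counts[lab[a]] + w
    }
  }
  attr(counts, "excluded") <- excluded
  attr(counts, "total") <- n
  attr(counts, "mode") <- mode
  counts
}

#' Build a site-by-sample count matrix
#'
#' @param assignments named list of count vectors from
#'   \code{\link{assign_reads}} (identical site labels), one per sample.
#' @return a numeric matrix (sites x samples) of class
#'   \code{SiteCountMatrix} with attributes \code{mode} and
#'   \code{excluded} (per-sample excluded read counts).
#' @export
site_count_matrix <- function(assignments) {
  stopifnot(length(assignments) >= 1)
  labs <- names(assignments[[1]])
  for (a in assignments) stopifnot(identical(names(a), labs))
  m <- do.call(cbind, lapply(assignments, as.numeric))
  rownames(m) <- labs
  colnames(m) <- names(assignments)
  structure(m, class = c("SiteCountMatrix", "matrix"),
            mode_assign = attr(assignments[[1]], "mode"),
            excluded = vapply(assignments, function(a)
              as.numeric(attr(a, "excluded") %||% 0), numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert pool assignment counts into site concentrations
#'
#' Each site's pool concentration is its read fraction times the total
#' RNA concentration of the binding reaction.
#'
#' @param pool_counts counts vector from \code{\link{assign_reads}} on the
#'   input pool (includes the no-site category).
#' @param total_conc total RNA concentration in nM (the RBNS standard is
#'   100 nM).
#' @return an object of class \code{PoolComposition}: list with
#'   \code{conc} (named nM vector, includes no-site) and \code{total}.
#' @export
pool_site_concentrations <- function(pool_counts, total_conc = 100) {
  stopifnot(total_conc > 0)
  tot <- sum(pool_counts)
  if (tot <= 0) stop("pool has zero assigned reads")
  conc <- as.numeric(pool_counts) / tot * total_conc
  names(conc) <- names(pool_counts)
  structure(list(conc = conc, total = total_conc), class = "PoolComposition")
}
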