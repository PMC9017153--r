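# Iterative de novo discovery of binding sites.
#
# The most enriched site type among the top-ranked k-mers is accepted when
# its Z-score in the ORIGINAL (unmasked) enrichment table reaches the
# 99.9th-percentile threshold and its motif is not significantly enriched
# in the no-protein control. Reads carrying an accepted motif are then
# masked in both the bound library and the pool so that "shadow" k-mers --
# enriched only through co-occurrence with a true site -- drop out of
# later iterations.
#
# The control filter operates on the motif, not on a single member k-mer:
# a motif's occurrences are spread over many flanking k-mer contexts, and
# any one context is a low-count observation whose control enrichment is
# dominated by sampling noise (the empirical 99.9th-percentile threshold
# guarantees ~0.1% of null k-mers exceed it). Aggregating to the motif --
# the unit discovery accepts and masks -- uses all of its occurrences and
# is tested with a one-sided two-proportion z-test at the same 0.1%
# significance convention.

#' Remove reads containing a motif
#'
#' @param sample a \code{\link{sequencing_sample}}.
#' @param motif motif string (RNA or DNA alphabet).
#' @return the sample with every read containing the motif removed;
#'   metadata unchanged.
#' @export
mask_reads <- function(sample, motif) {
  stopifnot(inherits(sample, "SequencingSample"))
  motif <- as_dna(motif)
  if (length(sample$inserts) && nchar(motif) > nchar(sample$inserts[1])) {
    stop("motif longer than the reads")
  }
  keep <- !grepl(motif, sample$inserts, fixed = TRUE)
  out <- sample
  out$inserts <- sample$inserts[keep]
  out
}

#' Iterative de novo site discovery
#'
#' Per iteration: (1) k-mer enrichments of bound versus pool are computed
#' on the current (masked) reads; (2) the \code{n_top} most enriched
#' k-mers are classified against the guide; (3) the most enriched site
#' type is selected (a site's enrichment is that of its single most
#' enriched k-mer); (4) the site is accepted iff its best member k-mer's
#' Z-score from the original unmasked table reaches the threshold AND its
#' motif is not significantly more frequent in the control than in the
#' pool (one-sided two-proportion z-test at the 0.1% level, the same
#' significance convention as the k-mer threshold); (5) reads containing
#' the site motif are masked in bound and pool and enrichments are
#' recomputed. The loop stops when step 4 fails.
#'
#' @param bound \code{\link{sequencing_sample}} from the binding reaction
#'   with the greatest protein concentration.
#' @param pool input-pool sample.
#' @param control no-protein control sample (or \code{NULL} to skip the
#'   control filter).
#' @param mirna a \code{\link{mirna}}.
#' @param k k-mer length (default 10).
#' @param region passed to \code{\link{count_kmers}}.
#' @param n_top number of top-enriched k-mers classified per iteration.
#' @param max_iter safety cap on iterations.
#' @return an object of class \code{DiscoveryResult}: list with
#'   \code{sites} (data.frame iteration/label/motif/enrichment/z_original),
#'   \code{masked_reads} (bound reads remaining after each iteration),
#'   \code{z_threshold} and \code{stop_reason}.
#' @export
discover_sites <- function(bound, pool, control = NULL, mirna, k = 10L,
                           region = "full", n_top = 100L, max_iter = 25L) {
  stopifnot(inherits(bound, "SequencingSample"),
            inherits(pool, "SequencingSample"))
  orig_tab <- enrichment_table(count_kmers(bound, k, region),
                               count_kmers(pool, k, region))
  if (!is.null(control)) stopifnot(inherits(control, "SequencingSample"))
  # one-sided two-proportion z for the motif's read frequency in the
  # (original) control versus the (original) pool
  ctrl_motif_z <- function(motif) {
    x_c <- sum(grepl(motif, control$inserts, fixed = TRUE))
    x_p <- sum(grepl(motif, pool$inserts, fixed = TRUE))
    n_c <- length(control$inserts); n_p <- length(pool$inserts)
    pbar <- (x_c + x_p) / (n_c + n_p)
    if (pbar <= 0 || pbar >= 1) return(0)
    (x_c / n_c - x_p / n_p) /
      sqrt(pbar * (1 - pbar) * (1 / n_c + 1 / n_p))
  }
  sites <- data.frame(iteration = integer(0), label = character(0),
                      motif = character(0), enrichment = numeric(0),
                      z_original = numeric(0), stringsAsFactors = FALSE)
  masked_reads <- integer(0)
  stop_reason <- "max-iterations"
  cur_bound <- bound; cur_pool <- pool
  cls_cache <- new.env(parent = emptyenv())
  for (iter in seq_len(max_iter)) {
    if (!length(cur_pool$inserts)) { stop_reason <- "pool exhausted"; break }
    tab <- if (iter == 1L) orig_tab else
      enrichment_table(count_kmers(cur_bound, k, region),
                       count_kmers(cur_pool, k, region))
    if (tab$degenerate) { stop_reason <- "degenerate enrichment"; break }
    R <- sort(tab$enrichment, decreasing = TRUE)
    top <- names(R)[seq_len(min(n_top, length(R)))]
    # classify top k-mers (cached across iterations)
    site_of <- vapply(top, function(m) {
      if (!is.null(cls_cache[[m]])) return(cls_cache[[m]]$label)
      st <- classify_kmer(m, mirna)
      cls_cache[[m]] <- if (is.null(st)) list(label = NA_character_) else st
      cls_cache[[m]]$label
    }, character(1))
    ok <- !is.na(site_of)
    if (!any(ok)) { stop_reason <- "no classifiable motif"; break }
    # site enrichment = enrichment of its single most enriched member k-mer
    best_per_site <- tapply(R[top][ok], site_of[ok], max)
    top_sites <- names(best_per_site)[best_per_site == max(best_per_site)]
    chosen <- sort(top_sites)[1L]  # lexicographic tie-break
    if (length(top_sites) > 1L) {
      message("tie between site types ", paste(top_sites, collapse = ", "),
              "; choosing ", chosen)
    }
    members <- top[ok][site_of[ok] == chosen]
    motif <- as_rna(cls_cache[[members[which.max(R[members])]]]$motif)
    # acceptance uses Z from the ORIGINAL unmasked table
    z_orig <- suppressWarnings(max(orig_tab$z[members], na.rm = TRUE))
    if (!is.finite(z_orig) || z_orig < orig_tab$z_threshold) {
      stop_reason <- "Z below threshold"; break
    }
    if (!is.null(control) &&
        ctrl_motif_z(as_dna(motif)) >= stats::qnorm(0.999)) {
      stop_reason <- sprintf("site '%s' enriched in no-protein control",
                             chosen)
      break
    }
    sites <- rbind(sites, data.frame(
      iteration = iter, label = chosen, motif = motif,
      enrichment = unname(best_per_site[chosen]),
      z_original = unname(z_orig), stringsAsFactors = FALSE))
    cur_bound <- mask_reads(cur_bound, motif)
    cur_pool <- mask_reads(cur_pool, motif)
    masked_reads <- c(masked_reads, length(cur_bound$inserts))
  }
  structure(list(sites = sites, masked_reads = masked_reads,
                 z_threshold = orig_tab$z_threshold,
                 stop_reason = stop_reason),
            class = "DiscoveryResult")
}

#' @export
print.DiscoveryResult <- function(x, ...) {
  cat(sprintf("DiscoveryResult: %d site(s), stop reason: %s\n",
              nrow(x$sites), x$stop_reason))
  if (nrow(x$sites)) print(x$sites)
  invisible(x)
}

#' Write a discovery report as TSV
#'
#' @param result a \code{DiscoveryResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_discovery_tsv <- function(result, path) {
  df <- result$sites
  df$stop_reason <- c(rep("", max(0, nrow(df) - 1)),
                      if (nrow(df)) result$stop_reason else character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
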