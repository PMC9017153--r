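# Synthetic data generation.
#
# The simulator produces site-category count matrices (and, separately,
# raw synthetic reads) for equilibrium binding series and kinetic time
# courses. Expected category concentrations come from the same binding
# model that the estimators fit; sequencing is modeled as drawing a fixed
# number of reads without replacement from the finite population of RNA
# molecules in the reaction (multivariate hypergeometric), so counting
# noise has the correct sub-multinomial variance. Default reaction
# conditions are fixed study conditions, not tuning knobs.

#' Molecule count of a concentration in a reaction volume
#'
#' @param conc_nM concentration(s) in nM.
#' @param volume reaction volume in liters (default 20 microliters).
#' @return number of molecules (numeric; not rounded).
#' @export
molecules_from_nM <- function(conc_nM, volume = 20e-6) {
  stopifnot(all(conc_nM >= 0), volume > 0)
  conc_nM * 1e-9 * volume * .AVOGADRO
}

# Multivariate hypergeometric draw: `depth` balls without replacement
# from an urn with `counts[i]` balls of color i. Sampled sequentially
# with rhyper; falls back to a multinomial approximation when the urn is
# too large for rhyper's integer arguments (the sampling fraction is then
# tiny, making with/without replacement indistinguishable).
.rmvhyper <- function(counts, depth) {
  counts <- round(counts)
  total <- sum(counts)
  depth <- round(depth)
  stopifnot(depth >= 0, depth <= total)
  if (depth == 0) return(numeric(length(counts)))
  if (total > .Machine$integer.max || depth > .Machine$integer.max) {
    return(as.numeric(rmultinom(1, depth, counts / total)))
  }
  out <- numeric(length(counts))
  remaining <- total
  left <- depth
  for (i in seq_along(counts)) {
    if (left == 0) break
    remaining <- remaining - counts[i]
    if (i == length(counts)) {
      out[i] <- left
      break
    }
    out[i] <- rhyper(1, counts[i], remaining, left)
    left <- left - out[i]
  }
  out
}

#' Subsample category counts without replacement
#'
#' @param counts non-negative category totals (molecules or reads).
#' @param depth number of draws (at most \code{sum(counts)}).
#' @return numeric vector of the same length summing to \code{depth}.
#' @export
subsample_counts <- function(counts, depth) {
  out <- .rmvhyper(counts, depth)
  names(out) <- names(counts)
  out
}

#' Default equilibrium study conditions
#'
#' A 100 nM random pool carrying four specific site categories at 15 pM
#' each (dissociation constants 5, 20, 100 and 500 pM; everything else is
#' a 5 nM no-site background), bound by serial dilutions of a 2.1 nM
#' protein stock (five 3.2-fold steps from dilution factor 0.4, plus a
#' no-protein control), with 0.1 nM non-specific recovery.
#'
#' @return list with \code{params} (an \code{\link{eq_params}}) and
#'   \code{design} (an \code{\link{eq_design}}).
#' @export
eq_study_conditions <- function() {
  sites <- c("site-A", "site-B", "site-C", "site-D")
  kd <- setNames(c(0.005, 0.02, 0.1, 0.5), sites)
  pool <- setNames(rep(0.015, 4), sites)
  pool <- c(pool, "no-site" = 100 - sum(pool))
  df <- 0.4 / 3.2^(0:4)
  df <- setNames(c(df, 0), paste0("df", seq_len(6)))
  list(params = eq_params(c(kd, "no-site" = 5), ago = 2.1,
                          background = 0.1),
       design = eq_design(pool, df))
}

#' Simulate an equilibrium binding series
#'
#' For every sample the expected recovered concentration of each site
#' category is converted into a molecule count in the reaction volume,
#' and \code{depth} reads are drawn from those molecules without
#' replacement.
#'
#' @param params an \code{\link{eq_params}} (default: the fixed study
#'   conditions of \code{\link{eq_study_conditions}}).
#' @param design an \code{\link{eq_design}} (same default).
#' @param depth reads per sample (default 2e7).
#' @param volume reaction volume in liters (default 20 microliters).
#' @param seed optional seed.
#' @return list with \code{counts} (a \code{SiteCountMatrix}-shaped
#'   sites x samples matrix), \code{expected} (expected concentrations,
#'   nM), \code{params} and \code{design}.
#' @export
simulate_equilibrium_counts <- function(params = NULL, design = NULL,
                                        depth = 2e7, volume = 20e-6,
                                        seed = NULL) {
  if (is.null(params) || is.null(design)) {
    std <- eq_study_conditions()
    if (is.null(params)) params <- std$params
    if (is.null(design)) design <- std$design
  }
  stopifnot(inherits(params, "EqParams"), inherits(design, "EqDesign"),
            depth > 0)
  .with_seed(seed, {
    sites <- names(params$kd)
    expected <- sapply(design$df, function(df) {
      as.numeric(predict_composition(params, design$pool, df))
    })
    rownames(expected) <- sites
    counts <- apply(expected, 2, function(x) {
      subsample_counts(molecules_from_nM(x, volume), depth)
    })
    rownames(counts) <- sites
    structure(list(counts = counts, expected = expected, params = params,
                   design = design), class = "SimulatedEquilibrium")
  })
}

#' Default kinetic study conditions
#'
#' 150 pM total protein sampled at 14 time points spanning 0 to 7200 s,
#' over the same pool as the equilibrium study. Two fixed parameter sets:
#' dataset 1 varies the association rate across sites
#' (kon = 0.1, 0.01, 0.001, 0.0001 per nM per s at koff mostly 0.01 per
#' s); dataset 2 fixes kon at 0.1 and varies koff
#' (1e-5, 1e-3, 0.01, 0.1 per s).
#'
#' @param dataset 1 or 2.
#' @return list with \code{params} (a \code{\link{kin_params}}) and
#'   \code{design} (a \code{\link{kin_design}}).
#' @export
kin_study_conditions <- function(dataset = 1L) {
  stopifnot(dataset %in% c(1L, 2L))
  sites <- c("site-A", "site-B", "site-C", "site-D")
  pool <- setNames(rep(0.015, 4), sites)
  pool <- c(pool, "no-site" = 100 - sum(pool))
  times <- c(0, 30, 60, 120, 240, 480, 900, 1800, 2700, 3600, 4500,
             5400, 6300, 7200)
  if (dataset == 1L) {
    kon <- setNames(c(0.1, 0.01, 0.001, 0.0001), sites)
    koff <- setNames(c(1e-4, 0.01, 0.01, 0.01), sites)
    kon <- c(kon, "no-site" = 0.0001)
  } else {
    kon <- setNames(rep(0.1, 4), sites)
    koff <- setNames(c(1e-5, 1e-3, 0.01, 0.1), sites)
    kon <- c(kon, "no-site" = 0.001)
  }
  koff <- c(koff, "no-site" = 10)
  list(params = kin_params(kon, koff, background = 0.1),
       design = kin_design(pool, protein = 0.15, times = times))
}

#' Simulate a kinetic binding time course
#'
#' @param params a \code{\link{kin_params}} (default: dataset-1 study
#'   conditions of \code{\link{kin_study_conditions}}).
#' @param design a \code{\link{kin_design}} (same default).
#' @param depth reads per time point (default 2e7).
#' @param volume reaction volume in liters (default 20 microliters).
#' @param seed optional seed.
#' @return list with \code{counts} (sites x time points), \code{expected}
#'   (nM), \code{params} and \code{design}.
#' @export
simulate_kinetic_counts <- function(params = NULL, design = NULL,
                                    depth = 2e7, volume = 20e-6,
                                    seed = NULL) {
  if (is.null(params) || is.null(design)) {
    std <- kin_study_conditions()
    if (is.null(params)) params <- std$params
    if (is.null(design)) design <- std$design
  }
  stopifnot(inherits(params, "KinParams"), inherits(design, "KinDesign"),
            depth > 0)
  .with_seed(seed, {
    sites <- names(params$kon)
    expected <- sapply(design$times, function(t) {
      as.numeric(predict_composition_t(params, design$pool,
                                       design$protein, t))
    })
    rownames(expected) <- sites
    counts <- apply(expected, 2, function(x) {
      subsample_counts(molecules_from_nM(x, volume), depth)
    })
    rownames(counts) <- sites
    structure(list(counts = counts, expected = expected, params = params,
                   design = design), class = "SimulatedKinetics")
  })
}

#' Generate synthetic random-pool reads with planted motifs
#'
#' Reads are uniform random sequences of the given length; a specified
#' fraction of reads has a motif planted at a uniformly random admissible
#' position (overwriting the random bases there). Useful for exercising
#' counting, enrichment and discovery on data with a known ground truth.
#'
#' @param n number of reads.
#' @param length read length (default 20).
#' @param planted named numeric vector: motif string (RNA or DNA) ->
#'   fraction of reads carrying it; fractions must sum to at most 1.
#'   \code{NULL} for a pure random pool.
#' @param base_weights sampling weights of A, C, G, T (default uniform).
#' @param sample_id,role,condition metadata for the returned sample.
#' @param seed optional seed.
#' @return a \code{\link{sequencing_sample}} whose \code{qc_report}
#'   records \code{n} reads passed; attribute \code{ground_truth} gives
#'   the planted motif of every read (\code{NA} for background reads).
#' @export
generate_synthetic_reads <- function(n, length = 20L, planted = NULL,
                                     base_weights = c(1, 1, 1, 1),
                                     sample_id = "synthetic",
                                     role = "pool", condition = "",
                                     seed = NULL) {
  stopifnot(n >= 1, length >= 1, length(base_weights) == 4,
            all(base_weights >= 0), sum(base_weights) > 0)
  if (!is.null(planted)) {
    stopifnot(!is.null(names(planted)), all(planted >= 0),
              sum(planted) <= 1 + 1e-12)
    motifs <- as_dna(names(planted))
    if (any(nchar(motifs) > length)) stop("planted motif longer than reads")
  }
  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    mat <- matrix(sample(bases, n * length, replace = TRUE,
                         prob = base_weights / sum(base_weights)),
                  nrow = n)
    truth <- rep(NA_character_, n)
    if (!is.null(planted)) {
      n_plant <- round(planted * n)
      idx_pool <- sample.int(n)   # assign reads to motifs disjointly
      offset <- 0L
      for (i in seq_along(motifs)) {
        if (n_plant[i] == 0) next
        rows <- idx_pool[offset + seq_len(n_plant[i])]
        offset <- offset + n_plant[i]
        chars <- strsplit(motifs[i], "")[[1]]
        w <- length(chars)
        pos <- sample.int(length - w + 1L, length(rows), replace = TRUE)
        for (r in seq_along(rows)) {
          mat[rows[r], pos[r]:(pos[r] + w - 1L)] <- chars
        }
        truth[rows] <- names(planted)[i]
      }
    }
    inserts <- apply(mat, 1, paste, collapse = "")
    smp <- sequencing_sample(sample_id, inserts, role = role,
                             condition = condition)
    attr(smp, "ground_truth") <- truth
    smp
  })
}
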