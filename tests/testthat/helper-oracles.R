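# Shared test oracles, implemented independently of the package internals.

# Central finite-difference gradient of a scalar function.
fd_gradient <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

# Plain bisection root finder (independent of stats::uniroot).
bisect_root <- function(f, lo, hi, iter = 200L) {
  flo <- f(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force overlapping k-mer counter.
brute_kmer_counts <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    for (i in seq_len(nchar(s) - k + 1)) {
      out <- c(out, substr(s, i, i + k - 1))
    }
  }
  table(out)
}

# Multinomial log-likelihood of a count matrix given per-sample
# probability columns (data-constant included, so only differences are
# comparable to the package cost).
multinom_loglik <- function(counts, probs) {
  sum(vapply(seq_len(ncol(counts)), function(j) {
    dmultinom(round(counts[, j]), prob = probs[, j], log = TRUE)
  }, numeric(1)))
}

# Quadratic (ligand-depletion) binding curve, reimplemented for titration
# round trips.
quad_binding <- function(r, kd_app, n, fmax) {
  fmax * (r + kd_app + n - sqrt((r + kd_app + n)^2 - 4 * r * n)) / (2 * n)
}

# Random equilibrium parameters in a numerically comfortable region.
random_eq_params <- function(sites) {
  m <- length(sites)
  kd <- exp(runif(m - 1, log(0.005), log(2)))
  eq_params(setNames(c(kd, exp(runif(1, log(1), log(20)))), sites),
            ago = exp(runif(1, log(0.5), log(10))),
            background = exp(runif(1, log(0.02), log(1))))
}

# Random kinetic parameters in a numerically comfortable region.
random_kin_params <- function(sites) {
  m <- length(sites)
  kin_params(setNames(exp(runif(m, log(1e-3), log(0.5))), sites),
             setNames(c(exp(runif(m - 1, log(1e-3), log(0.5))),
                        exp(runif(1, log(1), log(50)))), sites),
             background = exp(runif(1, log(0.02), log(1))))
}

# Tiny FASTQ writer (4-line records, Phred+33).
write_tiny_fastq <- function(path, ids, seqs, quals) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}
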