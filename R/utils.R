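#' @keywords internal
"_PACKAGE"

#' @import Biostrings
#' @importFrom stats optim uniroot quantile median sd cor rnorm rhyper rmultinom
#' @importFrom stats coef fitted residuals
#'   runif setNames nls resid coef
#' @importFrom utils write.table read.table read.delim
NULL

# Avogadro's number (mol^-1)
.AVOGADRO <- 6.02214076e23

# 3' adapter of the RBNS library design; the first three nucleotides anchor
# the insert/adapter boundary during quality control.
RBNS_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Normalize a nucleotide sequence to the DNA alphabet
#'
#' Uppercases and converts U to T so that RNA motifs and DNA reads can be
#' compared directly. T and U are treated as equivalent throughout.
#'
#' @param x character vector of sequences.
#' @return character vector in the \{A,C,G,T,N\} alphabet.
#' @export
as_dna <- function(x) {
  chartr("uU", "tT", toupper(x)) -> y
  toupper(y)
}

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' @param x character vector of sequences.
#' @return character vector in the \{A,C,G,U,N\} alphabet.
#' @export
as_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA (or DNA) sequences.
#' @return character vector of reverse complements, RNA alphabet.
#' @export
reverse_complement_rna <- function(x) {
  vapply(as_rna(x), function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

.check_alphabet <- function(x, extra = "") {
  bad <- grepl(paste0("[^ACGTUN", extra, "]"), toupper(x))
  if (any(bad)) {
    stop("invalid nucleotide alphabet in: ", paste(head(x[bad], 3), collapse = ", "))
  }
  invisible(TRUE)
}

# Seed handling: every stochastic routine takes an explicit `seed`; NULL
# leaves the RNG state untouched.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  eval.parent(substitute(expr))
}
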