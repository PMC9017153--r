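# Quality control of RBNS sequencing reads.
#
# Reads from an RBNS library are L-nt inserts (the randomized region plus
# any accessible constant flank) followed by the 3' adapter. A read is kept
# when the first three adapter nucleotides sit immediately after the insert,
# every base call passes the Phred cutoff and no N calls are present; kept
# reads are truncated to the insert.

#' Construct a SequencingSample
#'
#' A \code{SequencingSample} groups the QC-passed insert sequences of one
#' RBNS sample together with its role in the experiment and its QC report.
#'
#' @param sample_id character scalar.
#' @param inserts character vector of insert sequences (one alphabet,
#'   identical lengths). Stored uppercase in the DNA alphabet.
#' @param role one of \code{"pool"}, \code{"bound"}, \code{"control"},
#'   \code{"timepoint"}, \code{"no_protein_guide_only"}.
#' @param condition dilution factor (dimensionless), time (seconds) or
#'   \code{NA}.
#' @param qc_report named numeric vector of read counts:
#'   \code{total}, \code{passed} and one entry per failure reason.
#' @return an object of class \code{SequencingSample}.
#' @export
sequencing_sample <- function(sample_id, inserts,
                              role = c("pool", "bound", "control",
                                       "timepoint", "no_protein_guide_only"),
                              condition = NA_real_, qc_report = NULL) {
  role <- match.arg(role)
  inserts <- as_dna(as.character(inserts))
  if (length(inserts)) {
    .check_alphabet(inserts)
    w <- nchar(inserts)
    if (length(unique(w)) != 1L) {
      stop("all inserts of a sample must have identical length")
    }
  }
  if (is.null(qc_report)) {
    qc_report <- c(total = length(inserts), passed = length(inserts))
  }
  stopifnot(qc_report[["total"]] == sum(qc_report[names(qc_report) != "total"]))
  structure(
    list(sample_id = sample_id, role = role, condition = condition,
         inserts = inserts, qc_report = qc_report),
    class = "SequencingSample")
}

#' @export
print.SequencingSample <- function(x, ...) {
  cat(sprintf("SequencingSample '%s' (%s): %d inserts of %s nt\n",
              x$sample_id, x$role, length(x$inserts),
              if (length(x$inserts)) nchar(x$inserts[1]) else "?"))
  invisible(x)
}

#' Read a FASTQ file into a record table
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} for 4-line,
#' Phred+33 FASTQ, optionally gzip-compressed.
#'
#' @param path path to a FASTQ (or FASTQ.gz) file.
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @export
read_fastq_records <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Quality-filter and adapter-trim RBNS reads
#'
#' A read is retained iff (a) the first three adapter nucleotides occur at
#' positions \code{insert_length + 1 ... insert_length + 3}, (b) every base
#' call has Phred quality at least \code{min_quality}, and (c) no base call
#' is N. Retained reads are truncated to their first \code{insert_length}
#' nucleotides. Reads of exactly \code{insert_length} nt are treated as
#' already trimmed and skip the anchor check, so filtering is idempotent on
#' its own output.
#'
#' @param records data.frame with columns \code{seq} and \code{qual}
#'   (Phred+33), e.g. from \code{\link{read_fastq_records}}; an \code{id}
#'   column is used in error messages when present.
#' @param insert_length expected insert length in nt (default 20).
#' @param adapter 3' adapter sequence; only its first 3 nt anchor the check.
#' @param min_quality minimum Phred score for every base (default 20).
#' @inheritParams sequencing_sample
#' @return a \code{\link{sequencing_sample}} with the retained, trimmed
#'   inserts and a QC report of counts per failure reason.
#' @export
qc_filter_and_trim <- function(records, insert_length = 20L,
                               adapter = RBNS_ADAPTER, min_quality = 20L,
                               sample_id = "sample", role = "pool",
                               condition = NA_real_) {
  stopifnot(insert_length >= 1L, nchar(adapter) >= 3L)
  n <- nrow(records)
  if (is.null(n) || n == 0L) {
    return(sequencing_sample(sample_id, character(0), role, condition,
                             qc_report = c(total = 0, passed = 0)))
  }
  seqs <- toupper(records$seq)
  quals <- records$qual
  if (any(nchar(quals) != nchar(seqs))) {
    bad <- which(nchar(quals) != nchar(seqs))[1L]
    id <- if (!is.null(records$id)) records$id[bad] else paste("record", bad)
    stop("malformed FASTQ record (quality length != sequence length): ", id)
  }
  anchor <- substr(toupper(adapter), 1L, 3L)
  len <- nchar(seqs)
  reason <- rep(NA_character_, n)

  too_short <- len < insert_length | (len > insert_length & len < insert_length + 3L)
  reason[too_short] <- "too-short"

  need_anchor <- !too_short & len >= insert_length + 3L
  anchor_ok <- substr(seqs, insert_length + 1L, insert_length + 3L) == anchor
  reason[need_anchor & !anchor_ok] <- "no-adapter-anchor"

  open <- is.na(reason)
  # Phred+33: every base of the read as sequenced must pass the cutoff
  minq <- vapply(quals, function(q) {
    if (nchar(q) == 0L) return(Inf)
    min(utf8ToInt(q)) - 33L
  }, numeric(1), USE.NAMES = FALSE)
  reason[open & minq < min_quality] <- "low-quality"

  open <- is.na(reason)
  reason[open & grepl("N", seqs, fixed = TRUE)] <- "contains-N"

  keep <- is.na(reason)
  inserts <- substr(seqs[keep], 1L, insert_length)
  tab <- table(factor(reason[!keep],
                      levels = c("too-short", "no-adapter-anchor",
                                 "low-quality", "contains-N")))
  report <- c(total = n, passed = sum(keep), as.vector(tab))
  names(report) <- c("total", "passed", names(tab))
  sequencing_sample(sample_id, inserts, role, condition, qc_report = report)
}

#' Write a QC report as TSV
#'
#' @param sample a \code{SequencingSample}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(sample, path) {
  rep <- sample$qc_report
  df <- data.frame(reason = names(rep), count = as.numeric(rep))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
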