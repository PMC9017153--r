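# miRNA target-site grammar.
#
# A binding site is described by the guide positions it pairs (gX..gY,
# counted from the miRNA 5' end), an optional t1 identity (the target
# nucleotide opposite g1, recognized by a binding pocket rather than by
# pairing), and optional single-nucleotide edits: G:U wobbles, one
# non-wobble mismatch, one bulged target nucleotide, or a deletion of a
# guide position. Site labels follow the field's nomenclature: 8mer,
# 7mer-m8, 7mer-A1, 6mer, 6mer-A1, 5mer-A1, kmer-mX.Y for other spans,
# -wN for wobbles, bX.YN for bulges; mismatch (-xNnt) and deletion (-dN)
# suffixes are this package's convention.

.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")
.WOBBLE   <- c(G = "U", U = "G")   # guide base -> wobble target base

#' Construct a miRNA guide object
#'
#' @param name guide name, e.g. \code{"let-7a"}.
#' @param guide guide sequence 5' to 3', 18-26 nt, RNA alphabet (T accepted
#'   and converted).
#' @return an object of class \code{MiRNA}.
#' @export
mirna <- function(name, guide) {
  guide <- as_rna(guide)
  if (nchar(guide) < 18 || nchar(guide) > 26) {
    stop("guide length must be 18-26 nt")
  }
  if (grepl("[^ACGU]", guide)) stop("guide must be A/C/G/U only")
  structure(list(name = name, guide = guide,
                 chars = strsplit(guide, "")[[1]]),
            class = "MiRNA")
}

#' The let-7a guide sequence
#'
#' @return a \code{\link{mirna}} object for let-7a.
#' @export
let7a <- function() mirna("let-7a", "UGAGGUAGUAGGUUGUAUAGUU")

#' Construct a pairing specification
#'
#' @param start,end first and last paired guide positions (gX, gY).
#' @param t1 target nucleotide at position t1 (\code{"A"}, \code{"C"},
#'   \code{"G"}, \code{"U"}) or \code{NA}; only meaningful when
#'   \code{start == 2}.
#' @param wobbles integer vector of guide positions paired G:U.
#' @param mismatches named character vector, names = guide positions,
#'   values = target nucleotide opposite that position.
#' @param bulge \code{NULL} or \code{list(after = N, nt = "G")}: target
#'   nucleotide \code{nt} inserted between the positions pairing guide
#'   \code{N} and \code{N + 1}.
#' @param deletion integer vector of guide positions left unpaired
#'   (skipped) in the target; at most one of bulge/deletion may be set.
#' @return an object of class \code{PairingSpec}.
#' @export
pairing_spec <- function(start, end, t1 = NA_character_,
                         wobbles = integer(0), mismatches = character(0),
                         bulge = NULL, deletion = integer(0)) {
  stopifnot(start >= 1, start <= end)
  if (!is.na(t1)) {
    t1 <- as_rna(t1)
    stopifnot(t1 %in% c("A", "C", "G", "U"))
    if (start != 2) stop("t1 identity only applies to sites starting at g2")
  }
  if (!is.null(bulge) && length(deletion)) {
    stop("at most one of bulge/deletion per site")
  }
  edits <- c(wobbles, as.integer(names(mismatches)), deletion,
             if (!is.null(bulge)) c(bulge$after, bulge$after + 1))
  if (length(edits) && (any(edits < start) || any(edits > end))) {
    stop("edit positions outside the paired span [", start, ",", end, "]")
  }
  structure(list(start = as.integer(start), end = as.integer(end), t1 = t1,
                 wobbles = sort(as.integer(wobbles)),
                 mismatches = mismatches,
                 bulge = bulge, deletion = sort(as.integer(deletion))),
            class = "PairingSpec")
}

#' Target motif of a pairing specification
#'
#' The motif is the reverse complement of the paired guide span, written
#' 5' to 3' on the target, with wobble/mismatch substitutions, a bulged
#' nucleotide or deletions applied, and the t1 nucleotide appended at the
#' motif 3' end when specified.
#'
#' @param spec a \code{\link{pairing_spec}}.
#' @param mirna a \code{\link{mirna}}.
#' @return motif string, RNA alphabet, 5' to 3'.
#' @export
site_motif <- function(spec, mirna) {
  stopifnot(inherits(spec, "PairingSpec"), inherits(mirna, "MiRNA"))
  if (spec$end > length(mirna$chars)) stop("span exceeds guide length")
  pos <- setdiff(spec$start:spec$end, spec$deletion)
  target <- vapply(pos, function(p) {
    g <- mirna$chars[p]
    if (p %in% spec$wobbles) {
      w <- .WOBBLE[g]
      if (is.na(w)) stop("no wobble pairing possible at guide position ", p)
      unname(w)
    } else {
      unname(.RNA_COMP[g])
    }
  }, character(1))
  # target position j pairs guide position pos[n - j + 1]
  target <- rev(target)
  if (length(spec$mismatches)) {
    for (p in as.integer(names(spec$mismatches))) {
      j <- length(pos) - match(p, pos) + 1L
      if (is.na(j)) stop("mismatch position not in paired span")
      target[j] <- as_rna(spec$mismatches[[as.character(p)]])
    }
  }
  if (!is.null(spec$bulge)) {
    j1 <- length(pos) - match(spec$bulge$after + 1L, pos) + 1L
    if (is.na(j1)) stop("bulge flanking position not in paired span")
    target <- append(target, as_rna(spec$bulge$nt), after = j1)
  }
  if (!is.na(spec$t1)) target <- c(target, spec$t1)
  paste(target, collapse = "")
}

#' Canonical label of a pairing specification
#'
#' @inheritParams site_motif
#' @return label string.
#' @export
spec_label <- function(spec, mirna = NULL) {
  X <- spec$start; Y <- spec$end
  has_t1 <- !is.na(spec$t1)
  plain <- !length(spec$wobbles) && !length(spec$mismatches) &&
    is.null(spec$bulge) && !length(spec$deletion)
  # seed-context bulge sites carry the field's standalone bX.YN name
  if (!is.null(spec$bulge) && X == 2 && Y == 8 && has_t1 && spec$t1 == "A" &&
      !length(spec$wobbles) && !length(spec$mismatches)) {
    return(paste0("b", spec$bulge$after, ".", spec$bulge$after + 1,
                  spec$bulge$nt))
  }
  span_len <- Y - X + 1L
  if (has_t1) {
    base <- if (X == 2 && Y == 8 && spec$t1 == "A") "8mer"
      else if (X == 2 && Y == 7 && spec$t1 == "A") "7mer-A1"
      else if (X == 2 && Y == 6 && spec$t1 == "A") "6mer-A1"
      else if (X == 2 && Y == 5 && spec$t1 == "A") "5mer-A1"
      else paste0(span_len + 1L, "mer-m", X, ".", Y, "-", spec$t1, "1")
  } else {
    base <- if (X == 2 && Y == 8) "7mer-m8"
      else if (X == 2 && Y == 7) "6mer"
      else paste0(span_len, "mer-m", X, ".", Y)
  }
  if (length(spec$wobbles)) {
    base <- paste0(base, paste0("-w", spec$wobbles, collapse = ""))
  }
  if (length(spec$mismatches)) {
    base <- paste0(base, paste0("-x", names(spec$mismatches),
                                as_rna(unlist(spec$mismatches)), collapse = ""))
  }
  if (!is.null(spec$bulge)) {
    base <- paste0(base, "-b", spec$bulge$after, ".", spec$bulge$after + 1,
                   spec$bulge$nt)
  }
  if (length(spec$deletion)) {
    base <- paste0(base, "-d", paste(spec$deletion, collapse = "/"))
  }
  base
}

#' Canonical seed-site specifications
#'
#' The canonical site set: 8mer, 7mer-m8, 7mer-A1, 6mer and 6mer-A1.
#'
#' @param mirna a \code{\link{mirna}} (unused; kept for symmetry).
#' @return named list of \code{\link{pairing_spec}}s.
#' @export
canonical_site_specs <- function(mirna = NULL) {
  specs <- list(
    pairing_spec(2, 8, t1 = "A"),
    pairing_spec(2, 8),
    pairing_spec(2, 7, t1 = "A"),
    pairing_spec(2, 7),
    pairing_spec(2, 6, t1 = "A"))
  names(specs) <- vapply(specs, spec_label, character(1))
  specs
}

# --- classification cascade ------------------------------------------------

# Compare a target fragment (RNA chars, 5'->3') to the guide span starting
# at X. Position j of the fragment pairs guide position X + plen - j.
# Returns per-position status: "wc", "wobble" or "mm".
.pair_status <- function(tchars, gchars, X) {
  plen <- length(tchars)
  gpos <- X + plen - seq_len(plen)
  g <- gchars[gpos]
  wc <- .RNA_COMP[g] == tchars
  wob <- !wc & !is.na(.WOBBLE[g]) & .WOBBLE[g] == tchars
  status <- ifelse(wc, "wc", ifelse(wob, "wobble", "mm"))
  list(status = status, gpos = gpos)
}

# Candidates for one target fragment at one cascade stage. `t1_mode`
# interprets the fragment's 3'-terminal nucleotide as the t1 identity and
# pins the paired span to start at g2.
.stage_candidates_one <- function(tchars, gchars, stage, t1_mode, offset) {
  L <- length(gchars)
  t_len <- length(tchars)
  out <- list()
  if (t1_mode) {
    if (t_len < 5L) return(out)
    t1 <- tchars[t_len]
    pair <- tchars[-t_len]
    starts <- 2L
  } else {
    t1 <- NA_character_
    pair <- tchars
    starts <- NULL  # set per stage below
  }
  add <- function(X, wob = integer(0), mm = character(0), bulge = NULL,
                  n_edits = 0L) {
    plen <- length(pair) - if (!is.null(bulge)) 1L else 0L
    out[[length(out) + 1L]] <<- list(
      start = X, end = X + plen - 1L, t1 = t1, wobbles = wob,
      mismatches = mm, bulge = bulge, n_edits = n_edits, offset = offset)
  }
  span_starts <- function(plen) {
    if (t1_mode) { if (2L + plen - 1L <= L) 2L else integer(0) }
    else seq_len(max(0L, L - plen + 1L))
  }
  if (stage %in% c("perfect", "wobble", "mismatch")) {
    plen <- length(pair)
    for (X in span_starts(plen)) {
      st <- .pair_status(pair, gchars, X)
      s <- st$status
      # edits must be internal to the span: a wobble or mismatch at a
      # span boundary is indistinguishable from a shorter perfect site
      # with an unpaired flanking nucleotide, and the cascade
      # canonicalizes it to the shorter site
      ends_wc <- plen >= 3L && s[1L] == "wc" && s[plen] == "wc"
      if (stage == "perfect" && all(s == "wc")) {
        add(X)
      } else if (stage == "wobble" && any(s == "wobble") &&
                 !any(s == "mm") && ends_wc) {
        add(X, wob = sort(st$gpos[s == "wobble"]),
            n_edits = sum(s == "wobble"))
      } else if (stage == "mismatch" && sum(s == "mm") == 1L &&
                 !any(s == "wobble") && ends_wc) {
        j <- which(s == "mm")
        add(X, mm = setNames(pair[j], st$gpos[j]), n_edits = 1L)
      }
    }
  } else if (stage == "bulge") {
    internal <- seq_len(length(pair))
    internal <- internal[internal > 1L & internal < length(pair)]
    for (q in internal) {
      tm <- pair[-q]
      plen <- length(tm)
      for (X in span_starts(plen)) {
        st <- .pair_status(tm, gchars, X)
        if (all(st$status == "wc")) {
          N <- X + plen - q
          add(X, bulge = list(after = N, nt = pair[q]), n_edits = 1L)
        }
      }
    }
  }
  out
}

# Pick the best candidate: fewest edits, then guide span closest to g2
# (seed-proximal), then 5'-most span, then 5'-most sub-k-mer.
.pick_candidate <- function(cands) {
  o <- order(vapply(cands, `[[`, 0L, "n_edits"),
             abs(vapply(cands, `[[`, 0L, "start") - 2L),
             vapply(cands, `[[`, 0L, "start"),
             vapply(cands, `[[`, 0L, "offset"))
  cands[[o[1L]]]
}

#' Classify a k-mer against a miRNA guide
#'
#' Applies the discovery cascade: perfect complementarity of the full
#' k-mer to contiguous guide positions; else complementarity allowing a
#' single bulged target nucleotide; else allowing G:U wobble pairing; else
#' allowing one non-wobble mismatch (wobbles, mismatches and bulges must
#' be internal to the paired span -- a boundary edit is canonically the
#' shorter perfect site); else the same cascade on all
#' (k-1)-mers within the k-mer, then (k-2)-mers, down to 4-mers. The first
#' matching configuration wins. A 3'-terminal nucleotide adjacent to a
#' g2-anchored span is interpreted as the t1 identity.
#'
#' @param kmer target k-mer (4-12 nt, DNA or RNA alphabet).
#' @param mirna a \code{\link{mirna}}.
#' @return a \code{SiteType} (list with \code{label}, \code{spec},
#'   \code{motif}) or \code{NULL} when no configuration qualifies.
#' @export
classify_kmer <- function(kmer, mirna) {
  stopifnot(inherits(mirna, "MiRNA"))
  kmer <- as_rna(kmer)
  if (grepl("[^ACGU]", kmer)) stop("invalid alphabet in k-mer: ", kmer)
  k <- nchar(kmer)
  if (k < 4L || k > 12L) stop("k-mer length must be between 4 and 12")
  kchars <- strsplit(kmer, "")[[1]]
  gchars <- mirna$chars
  for (sublen in seq(k, 4L)) {
    offsets <- seq_len(k - sublen + 1L)
    for (stage in c("perfect", "bulge", "wobble", "mismatch")) {
      cands <- list()
      for (off in offsets) {
        sub <- kchars[off:(off + sublen - 1L)]
        cands <- c(cands,
                   .stage_candidates_one(sub, gchars, stage, t1_mode = TRUE,
                                         offset = off),
                   .stage_candidates_one(sub, gchars, stage, t1_mode = FALSE,
                                         offset = off))
      }
      if (length(cands)) {
        best <- .pick_candidate(cands)
        spec <- pairing_spec(best$start, best$end, t1 = best$t1,
                             wobbles = best$wobbles,
                             mismatches = best$mismatches,
                             bulge = best$bulge)
        return(structure(list(label = spec_label(spec), spec = spec,
                              motif = site_motif(spec, mirna)),
                         class = "SiteType"))
      }
    }
  }
  NULL
}

#' Enumerate site motifs for a set of pairing specifications
#'
#' Deletion specifications that generate identical motifs (deleting guide
#' position N or N+1 when the guide repeats a base) are merged under a
#' single "N/N+1" label; identical motifs under distinct non-deletion
#' labels raise an ambiguity error.
#'
#' @param mirna a \code{\link{mirna}}.
#' @param specs list of \code{\link{pairing_spec}}s.
#' @return named character vector, label -> motif (RNA alphabet).
#' @export
enumerate_site_motifs <- function(mirna, specs) {
  if (!length(specs)) return(setNames(character(0), character(0)))
  labels <- vapply(specs, spec_label, character(1))
  motifs <- vapply(specs, site_motif, character(1), mirna = mirna)
  is_del <- vapply(specs, function(s) length(s$deletion) > 0, logical(1))
  out_lab <- character(0); out_mot <- character(0)
  for (i in seq_along(specs)) {
    j <- match(motifs[i], out_mot)
    if (is.na(j)) {
      out_lab <- c(out_lab, labels[i]); out_mot <- c(out_mot, motifs[i])
    } else {
      prev <- match(out_mot[j], motifs)  # first spec with this motif
      if (is_del[i] && is_del[prev]) {
        d1 <- specs[[prev]]$deletion; d2 <- specs[[i]]$deletion
        merged <- sub("-d.*$", "", labels[prev])
        out_lab[j] <- paste0(merged, "-d",
                             paste(sort(unique(c(d1, d2))), collapse = "/"))
      } else {
        stop("ambiguous site motifs: '", labels[i], "' and '", out_lab[j],
             "' share motif ", motifs[i])
      }
    }
  }
  setNames(out_mot, out_lab)
}

#' Write a site table as TSV
#'
#' @param motifs named character vector (label -> motif).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_site_table <- function(motifs, path) {
  df <- data.frame(label = names(motifs), motif = unname(motifs))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
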