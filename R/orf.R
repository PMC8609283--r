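# ORF finding, Fickett TESTCODE coding potential and NMD candidacy.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the longest ORF in a transcript-strand sequence
#'
#' Scans the three forward reading frames for ATG-initiated open reading
#' frames ending in a stop codon (no internal stop) and reports the longest;
#' ties resolve to the 5'-most start. The stop codon is included in the ORF
#' span and length; the protein length excludes it. Codons containing N
#' never qualify as start or stop.
#'
#' @param seq character DNA string (alphabet A/C/G/T/N), transcription order
#' @return list: `has_orf`, `orf_start`, `orf_end` (0-based half-open,
#'   stop included), `orf_length` (nt), `protein_length` (aa)
#' @export
findOrf <- function(seq) {
  none <- list(has_orf = FALSE, orf_start = NA_integer_,
               orf_end = NA_integer_, orf_length = 0L,
               protein_length = 0L)
  L <- nchar(seq)
  if (L < 6) return(none)
  best_len <- 0L; best_start <- NA_integer_
  for (f in 0:2) {
    ncod <- (L - f) %/% 3
    if (ncod < 2) next
    starts <- f + seq_len(ncod) * 3L - 2L  # 1-based codon starts
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stop <- which(codons %in% STOP_CODONS)
    if (!length(atg) || !length(stop)) next
    prev <- 0L
    ai <- 1L
    for (s in stop) {
      # earliest ATG after the previous stop and before this stop
      while (ai <= length(atg) && atg[ai] <= prev) ai <- ai + 1L
      if (ai <= length(atg) && atg[ai] < s) {
        len <- (s - atg[ai] + 1L) * 3L
        st <- starts[atg[ai]] - 1L  # 0-based
        if (len > best_len || (len == best_len && st < best_start)) {
          best_len <- len
          best_start <- st
        }
      }
      prev <- s
    }
  }
  if (best_len == 0L) return(none)
  list(has_orf = TRUE, orf_start = best_start,
       orf_end = best_start + best_len, orf_length = best_len,
       protein_length = best_len %/% 3L - 1L)
}

# Fickett (1982) TESTCODE lookup tables. Position parameter: per base,
# max/(min+1) of the counts in the three codon positions; content parameter:
# base fraction. Each parameter maps to a probability-of-coding through the
# published intervals, and the weighted sum of the eight probabilities is
# the score.
FICKETT_POS_CUT <- c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9)
FICKETT_POS_PROB <- list(
  A = c(0.22, 0.20, 0.34, 0.45, 0.68, 0.58, 0.93, 0.84, 0.68, 0.94),
  C = c(0.23, 0.30, 0.33, 0.51, 0.48, 0.66, 0.81, 0.70, 0.70, 0.80),
  G = c(0.08, 0.08, 0.16, 0.27, 0.48, 0.53, 0.64, 0.74, 0.88, 0.90),
  T = c(0.09, 0.16, 0.20, 0.54, 0.44, 0.69, 0.68, 0.91, 0.97, 0.97))
FICKETT_CNT_CUT <- c(0.17, 0.19, 0.21, 0.23, 0.25, 0.27, 0.29, 0.31, 0.33)
FICKETT_CNT_PROB <- list(
  A = c(0.21, 0.81, 0.65, 0.67, 0.49, 0.62, 0.55, 0.44, 0.49, 0.28),
  C = c(0.31, 0.39, 0.44, 0.43, 0.59, 0.59, 0.64, 0.51, 0.64, 0.82),
  G = c(0.29, 0.33, 0.41, 0.41, 0.73, 0.64, 0.64, 0.47, 0.54, 0.40),
  T = c(0.58, 0.51, 0.69, 0.56, 0.75, 0.55, 0.40, 0.39, 0.24, 0.28))
FICKETT_POS_W <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_CNT_W <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

#' Fickett TESTCODE coding-potential score
#'
#' Computed on the full transcript sequence from the published position and
#' composition lookup tables. Returns `NA` for sequences shorter than two
#' codons.
#'
#' @param seq character DNA string
#' @return numeric score (roughly 0.2-1.6; higher = more coding-like)
#' @export
fickettScore <- function(seq) {
  L <- nchar(seq)
  if (L < 6) return(NA_real_)
  chars <- strsplit(seq, "")[[1]]
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    at <- which(chars == b)
    cnt <- tabulate(((at - 1L) %% 3L) + 1L, nbins = 3L)
    posval <- max(cnt) / (min(cnt) + 1)
    pbin <- findInterval(posval, FICKETT_POS_CUT) + 1L
    comp <- length(at) / L
    cbin <- findInterval(comp, FICKETT_CNT_CUT) + 1L
    score <- score + FICKETT_POS_W[[b]] * FICKETT_POS_PROB[[b]][pbin] +
      FICKETT_CNT_W[[b]] * FICKETT_CNT_PROB[[b]][cbin]
  }
  score
}

#' Coding call from a coding-potential score
#'
#' @param score numeric score(s)
#' @param cutoff threshold (default 0.364, the human CPAT-probability
#'   cutoff applied when external scores are supplied)
#' @param strict if `TRUE` the call requires `score > cutoff` (the mouse
#'   convention); default `FALSE` uses `score >= cutoff`
#' @return logical
#' @export
codingFlag <- function(score, cutoff = 0.364, strict = FALSE) {
  ifelse(is.na(score), FALSE, if (strict) score > cutoff else score >= cutoff)
}

#' NMD candidacy from ORF and junction structure
#'
#' A transcript is an NMD candidate when it has an ORF whose stop codon ends
#' more than `min_dist` nt upstream of the last exon-exon junction (in
#' transcript coordinates). Mono-exonic transcripts are never flagged.
#' `min_dist = 50` implements the canonical 50-nt rule; the default 0 flags
#' any stop strictly before the last junction.
#'
#' @param ts a [TranscriptSet]
#' @param id transcript id or index
#' @param orf output of [findOrf()] for that transcript
#' @param min_dist minimum stop-to-last-junction distance (nt)
#' @return logical
#' @export
nmdFlag <- function(ts, id, orf, min_dist = 0L) {
  if (!orf$has_orf) return(FALSE)
  lj <- lastJunctionPos(ts, id)
  if (is.na(lj)) return(FALSE)
  (lj - orf$orf_end) > min_dist
}

#' ORF, coding-potential and NMD table for a transcript set
#'
#' Runs [findOrf()], [fickettScore()] and [nmdFlag()] per transcript.
#' When an external score table is supplied (e.g. CPAT coding
#' probabilities) it takes precedence over the built-in Fickett score and
#' the provenance is recorded in `score_type`, so that probability cutoffs
#' are only applied to probability-type scores knowingly.
#'
#' @param ts a [TranscriptSet]
#' @param genome named [Biostrings::DNAStringSet]
#' @param coding_cutoff threshold passed to [codingFlag()]
#' @param coding_strict strict inequality flag passed to [codingFlag()]
#' @param external_scores optional named numeric vector of per-transcript
#'   coding scores
#' @param nmd_min_dist passed to [nmdFlag()]
#' @return `data.frame`: per-transcript ORF coordinates and length, protein
#'   length, stop-to-last-junction distance (positive = stop upstream of the
#'   last junction; `NA` for mono-exonic), coding score/flag/provenance and
#'   NMD flag
#' @export
predictOrfs <- function(ts, genome, coding_cutoff = 0.364,
                        coding_strict = FALSE, external_scores = NULL,
                        nmd_min_dist = 0L) {
  info <- ts@info
  n <- nrow(info)
  out <- data.frame(
    transcript_id = info$transcript_id,
    has_orf = FALSE, orf_start = NA_integer_, orf_end = NA_integer_,
    orf_length = 0L, protein_length = 0L,
    stop_to_last_junction = NA_integer_,
    coding_score = NA_real_, score_type = NA_character_,
    coding_flag = FALSE, nmd_flag = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    seq <- transcriptSequence(ts, i, genome)
    orf <- findOrf(seq)
    out$has_orf[i] <- orf$has_orf
    out$orf_start[i] <- orf$orf_start
    out$orf_end[i] <- orf$orf_end
    out$orf_length[i] <- orf$orf_length
    out$protein_length[i] <- orf$protein_length
    id <- info$transcript_id[i]
    if (!is.null(external_scores) && id %in% names(external_scores)) {
      out$coding_score[i] <- external_scores[[id]]
      out$score_type[i] <- "external"
    } else {
      out$coding_score[i] <- fickettScore(seq)
      out$score_type[i] <- "fickett"
    }
    out$coding_flag[i] <- codingFlag(out$coding_score[i], coding_cutoff,
                                     coding_strict)
    lj <- lastJunctionPos(ts, i)
    if (!is.na(lj) && orf$has_orf)
      out$stop_to_last_junction[i] <- lj - orf$orf_end
    out$nmd_flag[i] <- nmdFlag(ts, i, orf, min_dist = nmd_min_dist)
  }
  out
}
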