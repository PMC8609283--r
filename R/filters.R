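# Artifact filters and 5'/3' evidence annotations.

#' Remove 5'-degradation fragments
#'
#' A transcript is removed when another transcript on the same chromosome and
#' strand carries its junction chain as a contiguous proper suffix (in
#' transcription order) and their 3' ends lie within `delta3` nt. A
#' mono-exonic transcript is removed when it is contained in another
#' transcript's 3'-most exon with its 3' end within `delta3` nt. The witness
#' is sought in the full input set, which makes the filter idempotent.
#'
#' @param ts a [TranscriptSet]
#' @param delta3 3'-end tolerance in nt (default 100)
#' @return list with `kept` ([TranscriptSet]), `removed_fragment_ids`
#'   (character)
#' @export
removeFragments <- function(ts, delta3 = 100L) {
  info <- ts@info
  n <- nrow(info)
  removed <- logical(n)
  tts <- txTts(info)
  grp <- paste(info$chrom, info$strand)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    strand <- info$strand[idx[1]]
    for (a in idx) {
      ka <- info$n_exons[a] - 1L
      for (b in idx) {
        if (a == b) next
        if (abs(tts[a] - tts[b]) > delta3) next
        if (info$n_exons[a] >= 2) {
          kb <- info$n_exons[b] - 1L
          if (kb <= ka) next
          ia <- ts@introns[[a]]; ib <- ts@introns[[b]]
          # transcription-order suffix: genomic tail on "+", genomic head
          # on "-"
          rows <- if (strand == "+") (kb - ka + 1L):kb else 1L:ka
          if (all(ib[rows, 1] == ia[, 1]) && all(ib[rows, 2] == ia[, 2])) {
            removed[a] <- TRUE
            break
          }
        } else {
          exb <- ts@exons[[b]]
          last <- if (strand == "+") exb[nrow(exb), ] else exb[1, ]
          if (info$start[a] >= last[1] && info$end[a] <= last[2]) {
            removed[a] <- TRUE
            break
          }
        }
      }
    }
  }
  list(kept = ts[!removed],
       removed_fragment_ids = info$transcript_id[removed])
}

#' Intrapriming evidence: A-fraction downstream of the 3' end
#'
#' Computes the fraction of adenines, read on the transcript's strand, in the
#' `window` genomic bases immediately downstream of each 3' end. Transcripts
#' are flagged when the fraction is >= `threshold`. Windows truncated by a
#' chromosome end are computed on the available bases (with a warning); a
#' fully absent window yields `NA`.
#'
#' @param ts a [TranscriptSet]
#' @param genome named [Biostrings::DNAStringSet]
#' @param window window size in nt (default 20)
#' @param threshold flagging threshold (default 0.6; flagged at equality)
#' @return `data.frame`: `transcript_id`, `frac_a_downstream`,
#'   `intrapriming_flag`
#' @export
intraprimingScan <- function(ts, genome, window = 20L, threshold = 0.6) {
  info <- ts@info
  frac <- rep(NA_real_, nrow(info))
  for (i in seq_len(nrow(info))) {
    chrom <- info$chrom[i]
    if (!chrom %in% names(genome))
      stop("chromosome ", chrom, " absent from genome")
    len <- length(genome[[chrom]])
    if (info$strand[i] == "+") {
      s <- info$end[i]; e <- min(info$end[i] + window, len)
    } else {
      s <- max(info$start[i] - window, 0L); e <- info$start[i]
    }
    if (e - s < window)
      warning("3' flank of ", info$transcript_id[i],
              " truncated at chromosome end")
    if (e <= s) next
    seq <- genomeSubseq(genome, chrom, s, e, strand = info$strand[i])
    frac[i] <- lengths(regmatches(seq, gregexpr("A", seq))) / nchar(seq)
  }
  data.frame(transcript_id = info$transcript_id,
             frac_a_downstream = frac,
             intrapriming_flag = !is.na(frac) & frac >= threshold,
             stringsAsFactors = FALSE)
}

#' Remove intrapriming artifacts from a classified set
#'
#' Flagged transcripts are removed unless they are FSM: annotated 3' ends are
#' independently supported, so the filter targets novel-category artifacts.
#'
#' @param classification output of [classifyAll()] with intrapriming columns
#' @return list with `kept_ids` and `removed_intrapriming_ids`
#' @export
intraprimingFilter <- function(classification) {
  flagged <- !is.na(classification$intrapriming_flag) &
    classification$intrapriming_flag & classification$category != "FSM"
  list(kept_ids = classification$transcript_id[!flagged],
       removed_intrapriming_ids = classification$transcript_id[flagged])
}

#' Scan for polyA motifs near the 3' terminus
#'
#' Searches the transcript-strand sequence of the `window` nt ending at the
#' 3' terminus and reports, per transcript, the motif whose end lies closest
#' to the 3' end (distance in nt from the motif end to the terminus). Ties
#' are broken by motif list order.
#'
#' @param ts a [TranscriptSet]
#' @param genome named [Biostrings::DNAStringSet]
#' @param motifs character vector of uppercase DNA motifs
#' @param window scanned window in nt (default 50)
#' @return `data.frame`: `transcript_id`, `polya_motif`, `polya_dist`
#' @export
polyaMotifScan <- function(ts, genome, motifs, window = 50L) {
  info <- ts@info
  motif <- rep(NA_character_, nrow(info))
  dist <- rep(NA_integer_, nrow(info))
  if (length(motifs)) {
    if (any(!grepl("^[ACGT]+$", motifs)))
      stop("polyA motifs must be uppercase DNA")
    for (i in seq_len(nrow(info))) {
      seq <- transcriptSequence(ts, i, genome)
      tail_len <- min(window, nchar(seq))
      tl <- substr(seq, nchar(seq) - tail_len + 1L, nchar(seq))
      best_d <- NA_integer_; best_m <- NA_character_
      for (m in motifs) {
        hits <- gregexpr(m, tl, fixed = TRUE)[[1]]
        if (hits[1] == -1) next
        ends <- hits + nchar(m) - 1L
        d <- min(tail_len - ends)
        if (is.na(best_d) || d < best_d) {
          best_d <- d; best_m <- m
        }
      }
      motif[i] <- best_m
      dist[i] <- best_d
    }
  }
  data.frame(transcript_id = info$transcript_id, polya_motif = motif,
             polya_dist = dist, stringsAsFactors = FALSE)
}

#' Signed distance from each TSS to the nearest CAGE peak
#'
#' The distance is measured from the transcript's 5' boundary to the nearest
#' peak edge (0 when the TSS lies inside a peak). Negative values mean the
#' peak lies upstream of the TSS in transcription orientation. Equidistant
#' up/downstream peaks resolve to the upstream (negative) one.
#'
#' @param ts a [TranscriptSet]
#' @param peaks `data.frame` from [readBed()] (strand ignored)
#' @param within absolute distance for the `within_cage` flag (default 50)
#' @return `data.frame`: `transcript_id`, `dist_to_cage`, `within_cage`
#' @export
cageDistance <- function(ts, peaks, within = 50L) {
  info <- ts@info
  dist <- rep(NA_integer_, nrow(info))
  byc <- split(peaks, peaks$chrom)
  for (i in seq_len(nrow(info))) {
    p <- byc[[info$chrom[i]]]
    if (is.null(p) || nrow(p) == 0) next
    tss <- txTss(info[i, ])
    if (info$strand[i] == "+") {
      up <- tss - p$end      # >= 0 when peak upstream
      down <- p$start - tss  # >= 0 when peak downstream
    } else {
      up <- p$start - tss
      down <- tss - p$end
    }
    d <- ifelse(up >= 0, -up, ifelse(down >= 0, down, 0L))
    dist[i] <- d[order(abs(d), d)][1]
  }
  data.frame(transcript_id = info$transcript_id, dist_to_cage = dist,
             within_cage = !is.na(dist) & abs(dist) <= within,
             stringsAsFactors = FALSE)
}
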