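# Structural classification of query transcript models against a reference
# annotation. Junction chains are matched exactly (no wobble); category
# precedence is FSM > ISM > fusion > NIC > NNC > genic_genomic > genic_intron
# > antisense > intergenic, which makes the categories disjoint and
# exhaustive.

CATEGORY_LEVELS <- c("FSM", "ISM", "NIC", "NNC", "fusion", "antisense",
                     "intergenic", "genic_genomic", "genic_intron")

# For each query transcript, collect candidate genes:
#   ss_exon: same-strand genes with >= 1 bp exon-exon overlap
#   ss_span: same-strand genes whose extent overlaps the query span
#   os_span: opposite-strand genes whose extent overlaps the query span
candidate_genes <- function(ts, ann) {
  qinfo <- ts@info
  genes <- ann@genes
  rinfo <- ann@transcripts@info
  n <- nrow(qinfo)
  ss_exon <- replicate(n, character(0), simplify = FALSE)
  ss_span <- replicate(n, character(0), simplify = FALSE)
  os_span <- replicate(n, character(0), simplify = FALSE)
  if (n == 0 || nrow(genes) == 0)
    return(list(ss_exon = ss_exon, ss_span = ss_span, os_span = os_span))

  # flattened reference exon table tagged by gene
  rex_gene <- rep(rinfo$gene_id, rinfo$n_exons)
  rex_chrom <- rep(rinfo$chrom, rinfo$n_exons)
  rex_strand <- rep(rinfo$strand, rinfo$n_exons)
  rex <- do.call(rbind, ann@transcripts@exons)
  qex_tx <- rep(seq_len(n), qinfo$n_exons)
  qex_chrom <- rep(qinfo$chrom, qinfo$n_exons)
  qex_strand <- rep(qinfo$strand, qinfo$n_exons)
  qex <- do.call(rbind, ts@exons)

  for (ch in unique(qinfo$chrom)) {
    for (st in c("+", "-")) {
      qi <- which(qex_chrom == ch & qex_strand == st)
      if (!length(qi)) next
      qr <- IRanges::IRanges(qex[qi, 1] + 1L, qex[qi, 2])
      # exon-level overlap, same strand
      ri <- which(rex_chrom == ch & rex_strand == st)
      if (length(ri)) {
        rr <- IRanges::IRanges(rex[ri, 1] + 1L, rex[ri, 2])
        hits <- IRanges::findOverlaps(qr, rr)
        if (length(hits)) {
          tx <- qex_tx[qi[S4Vectors::queryHits(hits)]]
          gn <- rex_gene[ri[S4Vectors::subjectHits(hits)]]
          agg <- split(gn, tx)
          for (nm in names(agg))
            ss_exon[[as.integer(nm)]] <-
              union(ss_exon[[as.integer(nm)]], agg[[nm]])
        }
      }
      # span-level overlap against gene extents, both strands
      txs <- which(qinfo$chrom == ch & qinfo$strand == st)
      if (!length(txs)) next
      sp <- IRanges::IRanges(qinfo$start[txs] + 1L, qinfo$end[txs])
      for (gst in c("+", "-")) {
        gi <- which(genes$chrom == ch & genes$strand == gst)
        if (!length(gi)) next
        gr <- IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi])
        hits <- IRanges::findOverlaps(sp, gr)
        if (!length(hits)) next
        agg <- split(genes$gene_id[gi[S4Vectors::subjectHits(hits)]],
                     txs[S4Vectors::queryHits(hits)])
        tgt <- if (gst == st) "ss" else "os"
        for (nm in names(agg)) {
          k <- as.integer(nm)
          if (tgt == "ss") ss_span[[k]] <- union(ss_span[[k]], agg[[nm]])
          else os_span[[k]] <- union(os_span[[k]], agg[[nm]])
        }
      }
    }
  }
  list(ss_exon = ss_exon, ss_span = ss_span, os_span = os_span)
}

# deterministic best-match among candidate reference transcripts:
# minimal |dTSS| + |dTTS|, ties broken by lexicographic transcript id
best_ref_match <- function(cand_ids, q_tss, q_tts, rinfo) {
  idx <- match(cand_ids, rinfo$transcript_id)
  score <- abs(txTss(rinfo[idx, , drop = FALSE]) - q_tss) +
    abs(txTts(rinfo[idx, , drop = FALSE]) - q_tts)
  o <- order(score, cand_ids)
  cand_ids[o[1]]
}

# is `small` (k x 2 intron matrix, genomic order) a contiguous sub-block of
# `big` (m x 2, m > k)? returns start rows of matches (genomic order)
contiguous_match_positions <- function(small, big) {
  k <- nrow(small); m <- nrow(big)
  if (m <= k) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(m - k + 1)) {
    if (all(big[p:(p + k - 1), 1] == small[, 1]) &&
        all(big[p:(p + k - 1), 2] == small[, 2]))
      hits <- c(hits, p)
  }
  hits
}

classify_one <- function(ts, i, ann, cand) {
  info <- ts@info[i, ]
  rinfo <- ann@transcripts@info
  genes <- ann@genes
  q_tss <- txTss(info); q_tts <- txTts(info)
  ss_exon <- sort(cand$ss_exon[[i]])
  res <- list(category = NA_character_,
              associated_genes = character(0),
              associated_transcript = "novel",
              ism_subtype = NA_character_)

  order_genes <- function(g) {
    g[order(genes$start[match(g, genes$gene_id)], g)]
  }

  if (info$n_exons >= 2) {
    key <- ts@chainKey[i]
    hit <- ann@chainIndex[[key]]
    if (!is.null(hit)) {
      best <- best_ref_match(hit, q_tss, q_tts, rinfo)
      res$category <- "FSM"
      res$associated_transcript <- best
      res$associated_genes <- rinfo$gene_id[match(best, rinfo$transcript_id)]
      return(res)
    }
    # ISM: contiguous sub-chain of a reference chain, anchored anywhere
    qi <- ts@introns[[i]]
    cand_tx <- unlist(ann@geneTx[ss_exon], use.names = FALSE)
    matches <- character(0); positions <- integer(0); sizes <- integer(0)
    for (tid in cand_tx) {
      k <- match(tid, rinfo$transcript_id)
      if (rinfo$chrom[k] != info$chrom || rinfo$strand[k] != info$strand)
        next
      ri <- ann@transcripts@introns[[k]]
      pos <- contiguous_match_positions(qi, ri)
      if (length(pos)) {
        matches <- c(matches, tid)
        positions <- c(positions, pos[1])
        sizes <- c(sizes, nrow(ri))
      }
    }
    if (length(matches)) {
      best <- best_ref_match(matches, q_tss, q_tts, rinfo)
      b <- which(matches == best)[1]
      res$category <- "ISM"
      res$associated_transcript <- best
      res$associated_genes <- rinfo$gene_id[match(best, rinfo$transcript_id)]
      # subtype in transcription order: a transcription-order suffix keeps
      # the reference 3' junctions (the classic "fewer 5' exons" ISM)
      p <- positions[b]; m <- sizes[b]; k <- nrow(qi)
      at_g_end <- (p + k - 1) == m   # genomic right end
      at_g_start <- p == 1           # genomic left end
      suffix <- if (info$strand == "+") at_g_end else at_g_start
      prefix <- if (info$strand == "+") at_g_start else at_g_end
      res$ism_subtype <- if (suffix) "5prime_fragment"
        else if (prefix) "3prime_fragment" else "internal_fragment"
      return(res)
    }
    # fusion: exonic overlap with >= 2 genes with mutually disjoint extents
    if (length(ss_exon) >= 2) {
      gi <- match(ss_exon, genes$gene_id)
      o <- order(genes$start[gi])
      gs <- genes$start[gi][o]; ge <- genes$end[gi][o]
      if (all(ge[-length(ge)] <= gs[-1])) {
        res$category <- "fusion"
        res$associated_genes <- order_genes(ss_exon)
        return(res)
      }
    }
    if (length(ss_exon) >= 1) {
      pool_d <- sort(unique(unlist(lapply(ann@siteIndex[ss_exon],
                                          `[[`, "donors"))))
      pool_a <- sort(unique(unlist(lapply(ann@siteIndex[ss_exon],
                                          `[[`, "acceptors"))))
      jx <- txJunctions(ts, i)
      if (all(jx[, "donor"] %in% pool_d) &&
          all(jx[, "acceptor"] %in% pool_a)) {
        res$category <- "NIC"
        res$associated_genes <- order_genes(ss_exon)
        return(res)
      }
      if (any(jx[, "donor"] %in% pool_d) ||
          any(jx[, "acceptor"] %in% pool_a)) {
        res$category <- "NNC"
        res$associated_genes <- order_genes(ss_exon)
        return(res)
      }
      res$category <- "genic_genomic"
      res$associated_genes <- order_genes(ss_exon)
      return(res)
    }
  } else {
    # mono-exonic FSM: contained in a mono-exonic reference transcript of an
    # overlapping gene (containment tolerance 0)
    cand_tx <- unlist(ann@geneTx[ss_exon], use.names = FALSE)
    mono <- cand_tx[rinfo$n_exons[match(cand_tx, rinfo$transcript_id)] == 1]
    if (length(mono)) {
      k <- match(mono, rinfo$transcript_id)
      ok <- rinfo$start[k] <= info$start & rinfo$end[k] >= info$end
      if (any(ok)) {
        best <- best_ref_match(mono[ok], q_tss, q_tts, rinfo)
        res$category <- "FSM"
        res$associated_transcript <- best
        res$associated_genes <- rinfo$gene_id[match(best,
                                                    rinfo$transcript_id)]
        return(res)
      }
    }
    if (length(ss_exon) >= 1) {
      res$category <- "genic_genomic"
      res$associated_genes <- order_genes(ss_exon)
      return(res)
    }
  }

  # no shared exonic sequence on the same strand from here on
  ss_span <- cand$ss_span[[i]]
  if (length(ss_span)) {
    hosts <- character(0)
    for (g in ss_span) {
      intr <- ann@intronIndex[[g]]
      if (nrow(intr) &&
          any(intr[, 1] <= info$start & intr[, 2] >= info$end))
        hosts <- c(hosts, g)
    }
    if (length(hosts)) {
      res$category <- "genic_intron"
      res$associated_genes <- order_genes(hosts)
      return(res)
    }
  }
  os_span <- cand$os_span[[i]]
  if (length(os_span)) {
    res$category <- "antisense"
    res$associated_genes <- order_genes(os_span)
    return(res)
  }
  res$category <- "intergenic"
  res
}

ir_flag_one <- function(ts, i, ann, assoc_genes) {
  if (!length(assoc_genes)) return(FALSE)
  ex <- ts@exons[[i]]
  for (g in assoc_genes) {
    intr <- ann@intronIndex[[g]]
    if (!nrow(intr)) next
    for (e in seq_len(nrow(ex))) {
      if (any(ex[e, 1] < intr[, 1] & intr[, 2] < ex[e, 2]))
        return(TRUE)
    }
  }
  FALSE
}

#' Classify one query transcript against the reference
#'
#' Assigns exactly one structural category. Multi-exonic transcripts are FSM
#' when their junction chain equals a reference chain, ISM when it is a
#' contiguous sub-chain of one, fusion when their exons overlap two or more
#' same-strand genes with mutually disjoint extents, NIC when every donor and
#' acceptor is annotated in the associated gene(s), NNC when at least one
#' site is novel but something is shared, and otherwise fall through to
#' genic_genomic / genic_intron / antisense / intergenic. Mono-exonic
#' transcripts are FSM only when contained in a mono-exonic reference
#' transcript of an overlapping gene.
#'
#' @param ts a [TranscriptSet]
#' @param id transcript id or index
#' @param ann a [GenomeAnnotation]
#' @return one-row `data.frame` (see [classifyAll()] for columns)
#' @export
classifyTranscript <- function(ts, id, ann) {
  i <- if (is.character(id)) match(id, ts@info$transcript_id) else id
  classifyAll(ts[i], ann)
}

#' Classify all query transcripts and annotate evidence
#'
#' @param ts query [TranscriptSet]
#' @param ann reference [GenomeAnnotation]
#' @param genome optional genome ([Biostrings::DNAStringSet]); enables
#'   intrapriming and polyA annotation
#' @param cage optional CAGE peak `data.frame` from [readBed()]
#' @param polya_motifs optional character vector of motifs
#' @param lncrna_genes optional gene-id vector overriding the annotation's
#'   lncRNA biotype flags
#' @param intrapriming_window,intrapriming_threshold genomic window (nt)
#'   downstream of the 3' end and A-fraction threshold for the intrapriming
#'   flag (flagged when fraction >= threshold)
#' @param polya_window transcript-sequence window (nt) scanned for polyA
#'   motifs upstream of the 3' terminus
#' @param cage_within within-peak distance (bp) for the `within_cage` flag
#' @return `data.frame` with one row per transcript: category, associated
#'   gene(s) (semicolon-joined), associated transcript, ISM subtype, length,
#'   exon count, IR flag, lncRNA flag, novelty flag, and the optional
#'   CAGE/polyA/intrapriming annotations
#' @export
classifyAll <- function(ts, ann, genome = NULL, cage = NULL,
                        polya_motifs = NULL, lncrna_genes = NULL,
                        intrapriming_window = 20L,
                        intrapriming_threshold = 0.6,
                        polya_window = 50L, cage_within = 50L) {
  n <- length(ts)
  info <- ts@info
  if (n == 0) {
    return(data.frame(
      transcript_id = character(), chrom = character(),
      strand = character(), category = character(),
      associated_genes = character(), associated_transcript = character(),
      ism_subtype = character(), length = integer(), n_exons = integer(),
      ir_flag = logical(), lncrna_flag = logical(), novel_flag = logical(),
      dist_to_cage = integer(), within_cage = logical(),
      polya_motif = character(), polya_dist = integer(),
      frac_a_downstream = numeric(), intrapriming_flag = logical(),
      stringsAsFactors = FALSE))
  }
  cand <- candidate_genes(ts, ann)
  lnc <- if (is.null(lncrna_genes))
    ann@genes$gene_id[ann@genes$lncrna] else lncrna_genes
  out <- data.frame(
    transcript_id = info$transcript_id,
    chrom = info$chrom, strand = info$strand,
    category = NA_character_,
    associated_genes = NA_character_,
    associated_transcript = NA_character_,
    ism_subtype = NA_character_,
    length = info$length, n_exons = info$n_exons,
    ir_flag = FALSE, lncrna_flag = FALSE, novel_flag = NA,
    dist_to_cage = NA_integer_, within_cage = NA,
    polya_motif = NA_character_, polya_dist = NA_integer_,
    frac_a_downstream = NA_real_, intrapriming_flag = NA,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- classify_one(ts, i, ann, cand)
    out$category[i] <- r$category
    out$associated_genes[i] <- paste(r$associated_genes, collapse = ";")
    out$associated_transcript[i] <- r$associated_transcript
    out$ism_subtype[i] <- r$ism_subtype
    out$ir_flag[i] <- ir_flag_one(ts, i, ann, r$associated_genes)
    out$lncrna_flag[i] <- any(r$associated_genes %in% lnc)
  }
  out$novel_flag <- !(out$category %in% c("FSM", "ISM"))
  if (!is.null(cage)) {
    cd <- cageDistance(ts, cage, within = cage_within)
    out$dist_to_cage <- cd$dist_to_cage
    out$within_cage <- cd$within_cage
  }
  if (!is.null(genome)) {
    ip <- intraprimingScan(ts, genome, window = intrapriming_window,
                           threshold = intrapriming_threshold)
    out$frac_a_downstream <- ip$frac_a_downstream
    out$intrapriming_flag <- ip$intrapriming_flag
    if (!is.null(polya_motifs)) {
      pa <- polyaMotifScan(ts, genome, polya_motifs, window = polya_window)
      out$polya_motif <- pa$polya_motif
      out$polya_dist <- pa$polya_dist
    }
  }
  out
}
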