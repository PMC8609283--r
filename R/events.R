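# Local alternative-splicing event enumeration from splice-junction
# coordinates. Events are defined pairwise between transcripts of one gene
# grouping, in transcription order, then deduplicated by a type-specific
# coordinate key. IR is handled separately (against the reference
# annotation) by irAggregate().

EVENT_TYPES <- c("SE", "MX", "A5", "A3", "AF", "AL", "IR")
EVENT_TIE_ORDER <- c("AF", "SE", "A3", "A5", "AL", "MX", "IR")

# first/last exon in transcription order (genomic coordinates)
tx_first_exon <- function(ts, i) {
  ex <- ts@exons[[i]]
  if (ts@info$strand[i] == "+") ex[1, ] else ex[nrow(ex), ]
}
tx_last_exon <- function(ts, i) {
  ex <- ts@exons[[i]]
  if (ts@info$strand[i] == "+") ex[nrow(ex), ] else ex[1, ]
}

exons_disjoint <- function(e1, e2) e1[2] <= e2[1] || e2[2] <= e1[1]

# is the genomic segment [lo, hi) contained in one exon of transcript i?
segment_exonic <- function(ts, i, lo, hi) {
  ex <- ts@exons[[i]]
  any(ex[, 1] <= lo & ex[, 2] >= hi)
}

# transcription-order position: does exon a precede exon b?
precedes <- function(strand, a, b) {
  if (strand == "+") a[1] < b[1] else a[2] > b[2]
}

# events between one ordered pair (i, j) of transcripts; returns a list of
# lists(type, key, side) where side 1 supports the "inclusion" form
pair_events <- function(ts, i, j) {
  strand <- ts@info$strand[i]
  J1 <- txJunctions(ts, i); J2 <- txJunctions(ts, j)
  k1 <- nrow(J1); k2 <- nrow(J2)
  ev <- list()
  add <- function(type, key, inc, exc) {
    ev[[length(ev) + 1L]] <<- list(type = type, key = key, inc = inc,
                                   exc = exc)
  }
  fe1 <- tx_first_exon(ts, i); fe2 <- tx_first_exon(ts, j)
  le1 <- tx_last_exon(ts, i); le2 <- tx_last_exon(ts, j)
  af_pair <- k1 >= 1 && k2 >= 1 && J1[1, "acceptor"] == J2[1, "acceptor"] &&
    J1[1, "donor"] != J2[1, "donor"] && exons_disjoint(fe1, fe2)
  al_pair <- k1 >= 1 && k2 >= 1 &&
    J1[k1, "donor"] == J2[k2, "donor"] &&
    J1[k1, "acceptor"] != J2[k2, "acceptor"] && exons_disjoint(le1, le2)

  # SE: t_inc has consecutive junctions (d1,a1),(d2,a2); t_exc has (d1,a2)
  se_scan <- function(Jinc, Jexc, inc, exc) {
    ki <- nrow(Jinc)
    if (ki < 2) return()
    for (p in seq_len(ki - 1)) {
      d1 <- Jinc[p, "donor"]; a1 <- Jinc[p, "acceptor"]
      d2 <- Jinc[p + 1, "donor"]; a2 <- Jinc[p + 1, "acceptor"]
      if (any(Jexc[, "donor"] == d1 & Jexc[, "acceptor"] == a2))
        add("SE", paste(d1, a1, d2, a2, sep = ","), inc, exc)
    }
  }
  se_scan(J1, J2, i, j)
  se_scan(J2, J1, j, i)

  # MX: shared flanking donor/acceptor around two disjoint middle exons
  if (k1 >= 2 && k2 >= 2) {
    for (p in seq_len(k1 - 1)) {
      for (q in seq_len(k2 - 1)) {
        if (J1[p, "donor"] != J2[q, "donor"]) next
        if (J1[p + 1, "acceptor"] != J2[q + 1, "acceptor"]) next
        # middle exons in genomic coordinates
        m1 <- sort(c(J1[p, "acceptor"], J1[p + 1, "donor"]))
        m2 <- sort(c(J2[q, "acceptor"], J2[q + 1, "donor"]))
        if (!exons_disjoint(m1, m2)) next
        if (precedes(strand, m1, m2)) {
          key <- paste(J1[p, "donor"], J1[p, "acceptor"], J1[p + 1, "donor"],
                       J2[q, "acceptor"], J2[q + 1, "donor"],
                       J1[p + 1, "acceptor"], sep = ",")
          add("MX", key, i, j)
        } else {
          key <- paste(J1[p, "donor"], J2[q, "acceptor"], J2[q + 1, "donor"],
                       J1[p, "acceptor"], J1[p + 1, "donor"],
                       J1[p + 1, "acceptor"], sep = ",")
          add("MX", key, j, i)
        }
      }
    }
  }

  # A5 (alternative donor) and A3 (alternative acceptor)
  for (p in seq_len(k1)) {
    for (q in seq_len(k2)) {
      d1 <- J1[p, "donor"]; a1 <- J1[p, "acceptor"]
      d2 <- J2[q, "donor"]; a2 <- J2[q, "acceptor"]
      if (a1 == a2 && d1 != d2) {
        # suppressed when explained by an alternative-first-exon event
        if (!(p == 1 && q == 1 && af_pair)) {
          inner_is_1 <- if (strand == "+") d1 > d2 else d1 < d2
          seg <- sort(c(d1, d2))
          owner <- if (inner_is_1) i else j
          if (segment_exonic(ts, owner, seg[1], seg[2]))
            add("A5", paste(seg[1], seg[2], a1, sep = ","),
                owner, if (inner_is_1) j else i)
        }
      }
      if (d1 == d2 && a1 != a2) {
        if (!(p == k1 && q == k2 && al_pair)) {
          inner_is_1 <- if (strand == "+") a1 < a2 else a1 > a2
          seg <- sort(c(a1, a2))
          owner <- if (inner_is_1) i else j
          if (segment_exonic(ts, owner, seg[1], seg[2]))
            add("A3", paste(d1, seg[1], seg[2], sep = ","),
                owner, if (inner_is_1) j else i)
        }
      }
    }
  }

  if (af_pair) {
    first <- if (fe1[1] <= fe2[1]) fe1 else fe2
    second <- if (fe1[1] <= fe2[1]) fe2 else fe1
    key <- paste(first[1], first[2], second[1], second[2],
                 J1[1, "acceptor"], sep = ",")
    add("AF", key, if (fe1[1] <= fe2[1]) i else j,
        if (fe1[1] <= fe2[1]) j else i)
  }
  if (al_pair) {
    first <- if (le1[1] <= le2[1]) le1 else le2
    second <- if (le1[1] <= le2[1]) le2 else le1
    key <- paste(first[1], first[2], second[1], second[2],
                 J1[k1, "donor"], sep = ",")
    add("AL", key, if (le1[1] <= le2[1]) i else j,
        if (le1[1] <= le2[1]) j else i)
  }
  ev
}

#' Enumerate local alternative-splicing events
#'
#' Considers every unordered pair of multi-exonic transcripts within each
#' gene grouping and emits skipped-exon (SE), mutually-exclusive-exon (MX),
#' alternative 5'/3' splice-site (A5/A3) and alternative first/last exon
#' (AF/AL) events, defined on transcription-order splice-junction
#' coordinates and deduplicated by a type-specific coordinate key. A5/A3
#' events at the first/last junction that are already explained by an AF/AL
#' event are suppressed.
#'
#' @param ts a [TranscriptSet]
#' @param gene_of named character vector mapping transcript id to gene
#'   grouping (see [eventGroups()]); transcripts with `NA` are skipped
#' @return `data.frame`: `gene_id`, `event_type`, `key`,
#'   `inclusion_transcripts`, `exclusion_transcripts` (semicolon-joined),
#'   sorted by gene then type then key
#' @export
enumerateEvents <- function(ts, gene_of) {
  ids <- ts@info$transcript_id
  g <- gene_of[ids]
  keep <- !is.na(g) & ts@info$n_exons >= 2
  acc <- new.env(parent = emptyenv())
  for (gene in unique(g[keep])) {
    members <- which(keep & g == gene)
    if (length(members) < 2) next
    for (x in seq_along(members)) {
      for (y in seq_len(x - 1L)) {
        i <- members[x]; j <- members[y]
        if (ts@info$chrom[i] != ts@info$chrom[j] ||
            ts@info$strand[i] != ts@info$strand[j]) next
        for (e in pair_events(ts, i, j)) {
          kk <- paste(gene, e$type, e$key, sep = "|")
          cur <- if (exists(kk, envir = acc)) get(kk, envir = acc)
          else list(inc = character(0), exc = character(0))
          cur$inc <- union(cur$inc, ids[e$inc])
          cur$exc <- union(cur$exc, ids[e$exc])
          assign(kk, cur, envir = acc)
        }
      }
    }
  }
  kk <- ls(acc)
  if (!length(kk))
    return(data.frame(gene_id = character(), event_type = character(),
                      key = character(), inclusion_transcripts = character(),
                      exclusion_transcripts = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(kk, "|", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[[`, character(1), 1L),
    event_type = vapply(parts, `[[`, character(1), 2L),
    key = vapply(parts, `[[`, character(1), 3L),
    inclusion_transcripts = vapply(kk, function(k)
      paste(sort(get(k, envir = acc)$inc), collapse = ";"), character(1)),
    exclusion_transcripts = vapply(kk, function(k)
      paste(sort(get(k, envir = acc)$exc), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id, out$event_type, out$key), , drop = FALSE]
}

#' Gene groupings for event enumeration
#'
#' Transcripts take their first associated gene from the classification;
#' transcripts without an associated gene (novel-gene categories) are
#' grouped into same-strand overlap clusters labelled `novelgroup_<n>`.
#'
#' @param classification output of [classifyAll()]
#' @param ts the classified [TranscriptSet]
#' @return named character vector transcript id -> grouping
#' @export
eventGroups <- function(classification, ts) {
  first_gene <- vapply(strsplit(classification$associated_genes, ";",
                                fixed = TRUE),
                       function(x) if (length(x) && nzchar(x[1])) x[1]
                       else NA_character_, character(1))
  out <- setNames(first_gene, classification$transcript_id)
  un <- names(out)[is.na(out)]
  if (length(un)) {
    info <- ts@info[match(un, ts@info$transcript_id), ]
    cl <- 0L
    for (grp in split(seq_len(nrow(info)),
                      paste(info$chrom, info$strand))) {
      o <- grp[order(info$start[grp])]
      cur_end <- -1L
      for (k in o) {
        if (info$start[k] >= cur_end) {
          cl <- cl + 1L
          cur_end <- info$end[k]
        } else cur_end <- max(cur_end, info$end[k])
        out[un[k]] <- paste0("novelgroup_", cl)
      }
    }
  }
  out
}

#' Aggregate intron-retention calls per gene
#'
#' @param classification output of [classifyAll()]
#' @return list: `ir_transcripts` (ids with the IR flag), `ir_genes` (genes
#'   with >= 1 IR transcript), `only_ir_genes` (genes all of whose detected
#'   transcripts carry the IR flag)
#' @export
irAggregate <- function(classification) {
  first_gene <- vapply(strsplit(classification$associated_genes, ";",
                                fixed = TRUE),
                       function(x) if (length(x) && nzchar(x[1])) x[1]
                       else NA_character_, character(1))
  keep <- !is.na(first_gene)
  ir_tx <- classification$transcript_id[classification$ir_flag]
  byg <- split(classification$ir_flag[keep], first_gene[keep])
  ir_genes <- names(byg)[vapply(byg, any, logical(1))]
  only_ir <- names(byg)[vapply(byg, all, logical(1))]
  list(ir_transcripts = ir_tx, ir_genes = sort(ir_genes),
       only_ir_genes = sort(only_ir))
}

#' Per-gene event counts and predominant event type
#'
#' The predominant type is the one with the most distinct events in the
#' gene; ties resolve in the fixed order AF > SE > A3 > A5 > AL > MX > IR.
#' Genes with zero events are excluded.
#'
#' @param events output of [enumerateEvents()] (rows of type IR may be
#'   appended by the caller)
#' @return `data.frame`: `gene_id`, one count column per event type,
#'   `predominant`
#' @export
perGeneEventSummary <- function(events) {
  if (nrow(events) == 0)
    return(data.frame(gene_id = character(), stringsAsFactors = FALSE))
  tab <- table(events$gene_id,
               factor(events$event_type, levels = EVENT_TIE_ORDER))
  m <- as.data.frame.matrix(tab)
  pred <- apply(as.matrix(m), 1, function(x)
    EVENT_TIE_ORDER[which.max(x[EVENT_TIE_ORDER])])
  out <- data.frame(gene_id = rownames(m), m, predominant = pred,
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Write an event catalog as TSV
#'
#' One row per deduplicated event (gene, type, key coordinates, supporting
#' transcript lists), stably sorted by gene then key so that identical
#' catalogs produce byte-identical files.
#'
#' @param events output of [enumerateEvents()]
#' @param path output file
#' @export
writeEvents <- function(events, path) {
  out <- events[order(events$gene_id, events$event_type, events$key), ,
                drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event catalog written by [writeEvents()]
#' @param path TSV path
#' @export
readEvents <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
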