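# Independent oracles used to cross-check the implementation. These are
# deliberately naive, self-contained re-derivations of the rules: they work
# from raw exon matrices only (via txExons/txInfo data access) and share no
# index structures or helper code with the implementation.

# ---- brute-force structural classifier ------------------------------------

.or_introns <- function(ex) {
  n <- nrow(ex)
  if (n < 2) return(matrix(integer(0), 0, 2))
  cbind(ex[-n, 2], ex[-1, 1])
}

.or_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# exhaustive per-transcript classification against every reference
# transcript and gene
oracleClassify <- function(ts, ann) {
  qinfo <- txInfo(ts)
  rts <- refTranscripts(ann)
  rinfo <- txInfo(rts)
  genes <- refGenes(ann)
  rex <- lapply(seq_len(nrow(rinfo)), function(k) txExons(rts, k))
  rintr <- lapply(rex, .or_introns)
  rn <- vapply(rintr, nrow, integer(1))

  res <- data.frame(transcript_id = qinfo$transcript_id,
                    category = NA_character_,
                    associated_genes = NA_character_,
                    associated_transcript = NA_character_,
                    stringsAsFactors = FALSE)
  ends5 <- function(info) ifelse(info$strand == "+", info$start, info$end)
  ends3 <- function(info) ifelse(info$strand == "+", info$end, info$start)

  for (i in seq_len(nrow(qinfo))) {
    qex <- txExons(ts, i)
    qintr <- .or_introns(qex)
    chrom <- qinfo$chrom[i]; strand <- qinfo$strand[i]
    nq <- nrow(qintr)

    # genes with >= 1 bp exonic overlap, same strand (span prefilter only
    # prunes genes that cannot overlap at all)
    assoc <- character(0)
    g_cand <- which(genes$chrom == chrom & genes$strand == strand &
                      genes$start < qinfo$end[i] &
                      genes$end > qinfo$start[i])
    for (g in g_cand) {
      hit <- FALSE
      for (k in which(rinfo$gene_id == genes$gene_id[g])) {
        for (e in seq_len(nrow(rex[[k]]))) {
          for (qe in seq_len(nrow(qex))) {
            if (.or_overlap(qex[qe, 1], qex[qe, 2],
                            rex[[k]][e, 1], rex[[k]][e, 2])) {
              hit <- TRUE; break
            }
          }
          if (hit) break
        }
        if (hit) break
      }
      if (hit) assoc <- c(assoc, genes$gene_id[g])
    }
    ord_genes <- function(gg)
      paste(gg[order(genes$start[match(gg, genes$gene_id)], gg)],
            collapse = ";")
    pick_best <- function(cand) {
      ix <- match(cand, rinfo$transcript_id)
      sc <- abs(ends5(rinfo[ix, ]) - ends5(qinfo[i, ])) +
        abs(ends3(rinfo[ix, ]) - ends3(qinfo[i, ]))
      cand[order(sc, cand)][1]
    }

    set_res <- function(cat, gg, at) {
      res$category[i] <<- cat
      res$associated_genes[i] <<- gg
      res$associated_transcript[i] <<- at
    }

    if (nq >= 1) {
      # FSM: identical chain anywhere in the reference (a matching ref must
      # span the query's intron range, so the span prefilter loses nothing)
      fsm <- character(0)
      k_cand <- which(rinfo$chrom == chrom & rinfo$strand == strand &
                        rn == nq & rinfo$start <= qintr[1, 1] &
                        rinfo$end >= qintr[nq, 2])
      for (k in k_cand) {
        if (all(rintr[[k]] == qintr))
          fsm <- c(fsm, rinfo$transcript_id[k])
      }
      if (length(fsm)) {
        b <- pick_best(fsm)
        set_res("FSM", rinfo$gene_id[match(b, rinfo$transcript_id)], b)
        next
      }
      # ISM: contiguous sub-chain of a longer reference chain
      ism <- character(0)
      k_cand <- which(rinfo$chrom == chrom & rinfo$strand == strand &
                        rn > nq & rinfo$start <= qintr[1, 1] &
                        rinfo$end >= qintr[nq, 2])
      for (k in k_cand) {
        m <- nrow(rintr[[k]])
        for (p in 1:(m - nq + 1)) {
          if (all(rintr[[k]][p:(p + nq - 1), ] == qintr)) {
            ism <- c(ism, rinfo$transcript_id[k]); break
          }
        }
      }
      if (length(ism)) {
        b <- pick_best(ism)
        set_res("ISM", rinfo$gene_id[match(b, rinfo$transcript_id)], b)
        next
      }
      if (length(assoc) >= 2) {
        gi <- match(assoc, genes$gene_id)
        disjoint <- TRUE
        for (x in seq_along(gi)) for (y in seq_len(x - 1))
          if (.or_overlap(genes$start[gi[x]], genes$end[gi[x]],
                          genes$start[gi[y]], genes$end[gi[y]]))
            disjoint <- FALSE
        if (disjoint) { set_res("fusion", ord_genes(assoc), "novel"); next }
      }
      if (length(assoc)) {
        don <- integer(0); acc <- integer(0)
        for (k in which(rinfo$gene_id %in% assoc)) {
          ri <- rintr[[k]]
          if (!nrow(ri)) next
          if (strand == "+") { don <- c(don, ri[, 1]); acc <- c(acc, ri[, 2]) }
          else { don <- c(don, ri[, 2]); acc <- c(acc, ri[, 1]) }
        }
        qd <- if (strand == "+") qintr[, 1] else qintr[, 2]
        qa <- if (strand == "+") qintr[, 2] else qintr[, 1]
        if (all(qd %in% don) && all(qa %in% acc)) {
          set_res("NIC", ord_genes(assoc), "novel"); next
        }
        if (any(qd %in% don) || any(qa %in% acc)) {
          set_res("NNC", ord_genes(assoc), "novel"); next
        }
        set_res("genic_genomic", ord_genes(assoc), "novel"); next
      }
    } else {
      mono <- character(0)
      for (k in which(rinfo$gene_id %in% assoc)) {
        if (nrow(rex[[k]]) == 1 && rinfo$start[k] <= qinfo$start[i] &&
            rinfo$end[k] >= qinfo$end[i])
          mono <- c(mono, rinfo$transcript_id[k])
      }
      if (length(mono)) {
        b <- pick_best(mono)
        set_res("FSM", rinfo$gene_id[match(b, rinfo$transcript_id)], b)
        next
      }
      if (length(assoc)) {
        set_res("genic_genomic", ord_genes(assoc), "novel"); next
      }
    }
    # within one annotated intron, same strand
    hosts <- character(0)
    for (g in which(genes$chrom == chrom & genes$strand == strand &
                      genes$start < qinfo$end[i] &
                      genes$end > qinfo$start[i])) {
      for (k in which(rinfo$gene_id == genes$gene_id[g])) {
        ri <- rintr[[k]]
        if (nrow(ri) && any(ri[, 1] <= qinfo$start[i] &
                            ri[, 2] >= qinfo$end[i])) {
          hosts <- c(hosts, genes$gene_id[g]); break
        }
      }
    }
    if (length(hosts)) {
      set_res("genic_intron", ord_genes(unique(hosts)), "novel"); next
    }
    anti <- genes$gene_id[genes$chrom == chrom & genes$strand != strand &
                            genes$start < qinfo$end[i] &
                            genes$end > qinfo$start[i]]
    if (length(anti)) { set_res("antisense", ord_genes(anti), "novel"); next }
    set_res("intergenic", "", "novel")
  }
  res
}

# ---- naive pairwise AS-event oracle ---------------------------------------

# transcription-order junction list derived directly from an exon matrix
.or_tx_junc <- function(ex, strand) {
  intr <- .or_introns(ex)
  if (nrow(intr) == 0) return(intr)
  if (strand == "+") cbind(intr[, 1], intr[, 2])
  else cbind(rev(intr[, 2]), rev(intr[, 1]))
}

.or_in_exon <- function(ex, lo, hi) any(ex[, 1] <= lo & ex[, 2] >= hi)

# events for one gene given a list of exon matrices; returns key strings
# "TYPE|key" plus inclusion/exclusion support sets
oracleGeneEvents <- function(exlist, strand, ids) {
  out <- new.env(parent = emptyenv())
  note <- function(type, key, inc, exc) {
    kk <- paste(type, key, sep = "|")
    cur <- if (exists(kk, envir = out)) get(kk, envir = out)
    else list(inc = character(0), exc = character(0))
    cur$inc <- union(cur$inc, inc); cur$exc <- union(cur$exc, exc)
    assign(kk, cur, envir = out)
  }
  n <- length(exlist)
  J <- lapply(exlist, .or_tx_junc, strand = strand)
  firstx <- lapply(exlist, function(ex)
    if (strand == "+") ex[1, ] else ex[nrow(ex), ])
  lastx <- lapply(exlist, function(ex)
    if (strand == "+") ex[nrow(ex), ] else ex[1, ])
  disj <- function(a, b) a[2] <= b[1] || b[2] <= a[1]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    Ji <- J[[i]]; Jj <- J[[j]]
    ki <- nrow(Ji); kj <- nrow(Jj)
    if (ki == 0 || kj == 0) next
    afp <- Ji[1, 2] == Jj[1, 2] && Ji[1, 1] != Jj[1, 1] &&
      disj(firstx[[i]], firstx[[j]])
    alp <- Ji[ki, 1] == Jj[kj, 1] && Ji[ki, 2] != Jj[kj, 2] &&
      disj(lastx[[i]], lastx[[j]])
    # SE (i = inclusion)
    if (ki >= 2) for (p in 1:(ki - 1)) {
      if (any(Jj[, 1] == Ji[p, 1] & Jj[, 2] == Ji[p + 1, 2]))
        note("SE", paste(Ji[p, 1], Ji[p, 2], Ji[p + 1, 1], Ji[p + 1, 2],
                         sep = ","), ids[i], ids[j])
    }
    # MX (emit with i carrying the transcription-first middle exon)
    if (ki >= 2 && kj >= 2) for (p in 1:(ki - 1)) for (q in 1:(kj - 1)) {
      if (Ji[p, 1] != Jj[q, 1] || Ji[p + 1, 2] != Jj[q + 1, 2]) next
      m1 <- sort(c(Ji[p, 2], Ji[p + 1, 1]))
      m2 <- sort(c(Jj[q, 2], Jj[q + 1, 1]))
      if (!disj(m1, m2)) next
      first_is_i <- if (strand == "+") m1[1] < m2[1] else m1[2] > m2[2]
      if (first_is_i)
        note("MX", paste(Ji[p, 1], Ji[p, 2], Ji[p + 1, 1], Jj[q, 2],
                         Jj[q + 1, 1], Ji[p + 1, 2], sep = ","),
             ids[i], ids[j])
    }
    # A5 / A3 over every junction pair
    for (p in seq_len(ki)) for (q in seq_len(kj)) {
      if (Ji[p, 2] == Jj[q, 2] && Ji[p, 1] != Jj[q, 1] &&
          !(p == 1 && q == 1 && afp)) {
        inner_i <- if (strand == "+") Ji[p, 1] > Jj[q, 1]
        else Ji[p, 1] < Jj[q, 1]
        if (inner_i) {
          seg <- sort(c(Ji[p, 1], Jj[q, 1]))
          if (.or_in_exon(exlist[[i]], seg[1], seg[2]))
            note("A5", paste(seg[1], seg[2], Ji[p, 2], sep = ","),
                 ids[i], ids[j])
        }
      }
      if (Ji[p, 1] == Jj[q, 1] && Ji[p, 2] != Jj[q, 2] &&
          !(p == ki && q == kj && alp)) {
        inner_i <- if (strand == "+") Ji[p, 2] < Jj[q, 2]
        else Ji[p, 2] > Jj[q, 2]
        if (inner_i) {
          seg <- sort(c(Ji[p, 2], Jj[q, 2]))
          if (.or_in_exon(exlist[[i]], seg[1], seg[2]))
            note("A3", paste(Ji[p, 1], seg[1], seg[2], sep = ","),
                 ids[i], ids[j])
        }
      }
    }
    if (afp && firstx[[i]][1] <= firstx[[j]][1])
      note("AF", paste(firstx[[i]][1], firstx[[i]][2], firstx[[j]][1],
                       firstx[[j]][2], Ji[1, 2], sep = ","),
           ids[i], ids[j])
    if (alp && lastx[[i]][1] <= lastx[[j]][1])
      note("AL", paste(lastx[[i]][1], lastx[[i]][2], lastx[[j]][1],
                       lastx[[j]][2], Ji[ki, 1], sep = ","),
           ids[i], ids[j])
  }
  kk <- ls(out)
  if (!length(kk))
    return(data.frame(event_type = character(), key = character(),
                      inclusion_transcripts = character(),
                      exclusion_transcripts = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(kk, "|", fixed = TRUE)
  data.frame(
    event_type = vapply(parts, `[[`, character(1), 1L),
    key = vapply(parts, `[[`, character(1), 2L),
    inclusion_transcripts = vapply(kk, function(k)
      paste(sort(get(k, envir = out)$inc), collapse = ";"), character(1)),
    exclusion_transcripts = vapply(kk, function(k)
      paste(sort(get(k, envir = out)$exc), collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# ---- exhaustive ORF oracle ------------------------------------------------

oracleLongestOrf <- function(seq) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (s in seq_len(max(L - 5, 0))) {
    if (paste(ch[s:(s + 2)], collapse = "") != "ATG") next
    p <- s + 3
    while (p + 2 <= L) {
      cod <- paste(ch[p:(p + 2)], collapse = "")
      if (cod %in% stops) {
        len <- p + 3 - s
        if (is.null(best) || len > best$len ||
            (len == best$len && s < best$start))
          best <- list(start = s, len = len)
        break
      }
      p <- p + 3
    }
  }
  if (is.null(best)) return(list(has_orf = FALSE))
  list(has_orf = TRUE, orf_start = best$start - 1L,
       orf_end = best$start - 1L + best$len, orf_length = best$len)
}

# ---- exact rank-sum oracle by exhaustive labeling enumeration -------------

oracleWilcoxonExact <- function(x, y) {
  all <- c(x, y)
  nx <- length(x); n <- length(all)
  r <- rank(all)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  p <- if (w_obs > mu) 2 * mean(ws >= w_obs) else 2 * mean(ws <= w_obs)
  min(1, p)
}

# ---- small random-instance builders ---------------------------------------

# random gene: exon pool plus transcripts as random sub-chains with
# occasional donor/acceptor shifts, for event-oracle comparisons
randomEventGene <- function(n_tx = NULL, strand = NULL) {
  n_ex <- sample(4:8, 1)
  ex <- matrix(0L, n_ex, 2)
  pos <- sample(50:200, 1)
  for (k in seq_len(n_ex)) {
    len <- sample(60:180, 1)
    ex[k, ] <- c(pos, pos + len)
    pos <- pos + len + sample(120:400, 1)
  }
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  if (is.null(n_tx)) n_tx <- sample(2:6, 1)
  exlist <- list()
  for (t in seq_len(n_tx)) {
    keep <- sort(sample(seq_len(n_ex), sample(2:n_ex, 1)))
    m <- ex[keep, , drop = FALSE]
    # random small boundary shifts into introns
    if (nrow(m) >= 2 && stats::runif(1) < 0.5) {
      k <- sample(nrow(m) - 1, 1)
      gap <- m[k + 1, 1] - m[k, 2]
      if (gap > 20) {
        d <- sample(5:min(40, gap - 10), 1)
        if (stats::runif(1) < 0.5) m[k, 2] <- m[k, 2] + d
        else m[k + 1, 1] <- m[k + 1, 1] - d
      }
    }
    exlist[[t]] <- m
  }
  list(exons = exlist, strand = strand,
       ids = sprintf("t%02d", seq_len(n_tx)))
}

# TranscriptSet from a randomEventGene()
eventGeneToSet <- function(g, gene = "gX", chrom = "chr1") {
  df <- do.call(rbind, lapply(seq_along(g$exons), function(t)
    data.frame(transcript_id = g$ids[t], gene_id = gene, chrom = chrom,
               strand = g$strand, start = g$exons[[t]][, 1],
               end = g$exons[[t]][, 2], stringsAsFactors = FALSE)))
  makeTranscriptSet(df)
}

# small simulation shared by several tests
smallSimConfig <- function(seed) {
  simulationConfig(seed = seed,
    category_quota = c(FSM = 12L, ISM = 6L, NIC = 8L, NNC = 6L,
                       fusion = 4L, antisense = 4L, intergenic = 4L,
                       genic_genomic = 4L, genic_intron = 4L),
    event_quota = c(SE = 2L, MX = 2L, A5 = 2L, A3 = 2L, AF = 2L, AL = 2L),
    n_ir_genes = 4L, n_nmd_genes = 3L, n_nonnmd_genes = 3L,
    n_fragment_multi = 3L, n_fragment_mono = 2L, n_intrapriming = 3L,
    n_dtu_genes = 4L, chrom_len = 600000L)
}
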