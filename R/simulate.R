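# Seeded synthetic-data generator. Gene architectures are designed on a
# transcription-order axis and mirrored onto the genome for minus-strand
# genes, so every planted structure (category, AS event, ORF/NMD layout,
# artifact) has an exact, unambiguous truth label. The generator's defaults
# define the study conditions exercised by the test suite.

rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

#' Simulation configuration
#'
#' All quotas and ranges for the synthetic dataset. A fixed `seed` makes
#' every output byte-for-byte reproducible.
#'
#' @param seed integer RNG seed
#' @param category_quota named integer vector: queries per plain structural
#'   category (FSM, ISM, NIC, NNC, fusion, antisense, intergenic,
#'   genic_genomic, genic_intron)
#' @param event_quota named integer vector: single-event genes per AS type
#'   (SE, MX, A5, A3, AF, AL); each contributes two FSM queries
#' @param n_ir_genes genes with one intron-retaining (NIC) query
#' @param n_nmd_genes,n_nonnmd_genes genes with a designed ORF whose stop
#'   falls before / after the last junction (FSM queries)
#' @param n_fragment_multi,n_fragment_mono 5'-degradation fragments planted
#'   as suffix truncations / mono-exonic 3' remnants of a host FSM query
#' @param n_intrapriming genes with one NIC query over an A-rich genomic
#'   tract downstream of its 3' end
#' @param exon_len,intron_len,gene_gap,fusion_gap integer ranges (nt)
#' @param ref_extra range of additional reference transcripts per ordinary
#'   gene (beyond the full-chain transcript)
#' @param tss_jitter_max maximum FSM TSS jitter (nt, bounded by exon length
#'   so junction chains are untouched)
#' @param lncrna_fraction fraction of ordinary genes flagged as lncRNA
#' @param cage_sd,cage_width CAGE-peak TSS jitter SD and peak width (bp)
#' @param chrom_len chromosome length (nt)
#' @param depth sequencing depth per sample (full-length reads)
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2)
#' @param group_design named integer vector of samples per group
#' @param n_dtu_genes event genes given a planted isoform switch
#' @param dtu_tpm the two swapped group mean TPM levels
#' @param base_tpm_meanlog,base_tpm_sdlog log-normal target TPM for
#'   background transcripts
#' @return a `list` of class `isoscope_sim_config`
#' @export
simulationConfig <- function(seed = 1L,
    category_quota = c(FSM = 150L, ISM = 100L, NIC = 150L, NNC = 120L,
                       fusion = 40L, antisense = 40L, intergenic = 40L,
                       genic_genomic = 40L, genic_intron = 40L),
    event_quota = c(SE = 12L, MX = 12L, A5 = 12L, A3 = 12L, AF = 12L,
                    AL = 12L),
    n_ir_genes = 30L, n_nmd_genes = 25L, n_nonnmd_genes = 25L,
    n_fragment_multi = 30L, n_fragment_mono = 10L, n_intrapriming = 30L,
    exon_len = c(80L, 260L), intron_len = c(150L, 700L),
    gene_gap = c(1500L, 2500L), fusion_gap = c(300L, 800L),
    ref_extra = c(1L, 3L), tss_jitter_max = 60L,
    lncrna_fraction = 0.1, cage_sd = 15, cage_width = 30L,
    chrom_len = 3000000L,
    depth = 200000L, nb_dispersion = 0.3,
    group_design = c(fetal = 4L, adult = 3L),
    n_dtu_genes = 15L, dtu_tpm = c(60, 5),
    base_tpm_meanlog = log(150), base_tpm_sdlog = 1) {
  cfg <- as.list(environment())
  if (any(category_quota < 0) || any(event_quota < 0))
    stop("quotas must be non-negative")
  if (cfg$category_quota[["FSM"]] <
      cfg$category_quota[["antisense"]] +
      cfg$category_quota[["genic_genomic"]] +
      cfg$category_quota[["genic_intron"]])
    stop("FSM quota must cover the overlay quotas (antisense, genic_genomic,
         genic_intron host genes)")
  if (cfg$n_dtu_genes > sum(event_quota))
    stop("n_dtu_genes exceeds the number of event genes")
  class(cfg) <- "isoscope_sim_config"
  cfg
}

#' Category totals implied by a simulation configuration
#'
#' Accounts for the queries contributed outside the plain category quota:
#' NMD and fragment-host genes emit FSM queries, each AS-event gene emits
#' two, and IR/intrapriming genes emit NIC queries.
#'
#' @param config a [simulationConfig()]
#' @return named integer vector over the nine categories
#' @export
expectedCategoryCounts <- function(config) {
  q <- config$category_quota
  q[["FSM"]] <- q[["FSM"]] + config$n_nmd_genes + config$n_nonnmd_genes +
    config$n_fragment_multi + config$n_fragment_mono +
    2L * sum(config$event_quota)
  q[["NIC"]] <- q[["NIC"]] + config$n_ir_genes + config$n_intrapriming
  q
}

# ---- transcription-space architecture builders ----------------------------

make_layout <- function(n, cfg) {
  el <- cfg$exon_len; il <- cfg$intron_len
  ex <- matrix(0L, n, 2)
  pos <- 0L
  for (k in seq_len(n)) {
    len <- rint(el[1], el[2])
    ex[k, ] <- c(pos, pos + len)
    pos <- pos + len + if (k < n) rint(il[1], il[2]) else 0L
  }
  ex
}

# drop distinct random subsets of internal exons to form extra reference
# transcripts; rejection-sampled with a cap
extra_ref_drops <- function(n_exons, n_extra) {
  if (n_exons < 3 || n_extra < 1) return(list())
  internal <- 2:(n_exons - 1)
  seen <- character(0)
  out <- list()
  tries <- 0L
  while (length(out) < n_extra && tries < 50L) {
    tries <- tries + 1L
    k <- rint(1L, min(2L, length(internal)))
    dr <- sort(sample(internal, k))
    key <- paste(dr, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- dr
  }
  if (length(out) < n_extra)
    stop("could not sample distinct reference structures within cap")
  out
}

arch_ordinary <- function(role, cfg) {
  n <- switch(role,
              fsm = rint(4L, 8L), ism = rint(5L, 8L), nic = rint(5L, 8L),
              nnc = rint(4L, 7L), ir = rint(5L, 8L),
              intrapriming = rint(5L, 8L), fragment_multi = rint(4L, 7L),
              rint(4L, 8L))
  ex <- make_layout(n, cfg)
  refs <- list(ex)
  if (role %in% c("fsm", "nnc")) {
    for (dr in extra_ref_drops(n, rint(cfg$ref_extra[1], cfg$ref_extra[2])))
      refs[[length(refs) + 1L]] <- ex[-dr, , drop = FALSE]
  } else if (role %in% c("ism", "nic", "ir", "intrapriming")) {
    refs[[2]] <- ex[-2, , drop = FALSE]
  }
  list(role = role, n = n, ex = ex, refs = refs)
}

arch_nmd <- function(cfg, nmd) {
  lens <- c(rint(180L, 260L), rint(150L, 220L), rint(220L, 300L))
  ex <- matrix(0L, 3, 2)
  pos <- 0L
  for (k in 1:3) {
    ex[k, ] <- c(pos, pos + lens[k])
    pos <- pos + lens[k] + if (k < 3) rint(cfg$intron_len[1],
                                           cfg$intron_len[2]) else 0L
  }
  L <- sum(lens)
  last_junc <- lens[1] + lens[2]
  stop_end <- if (nmd) last_junc - 30L else last_junc + 60L
  s0 <- (stop_end %% 3L) + 6L
  body_len <- stop_end - s0 - 6L
  filler <- function(len) {
    if (len <= 0) return("")
    substr(strrep("CCG", ceiling(len / 3) + 1L), 1L, len)
  }
  seq <- paste0(filler(s0), "ATG", strrep("GGC", body_len %/% 3L), "TAA",
                filler(L - stop_end))
  stopifnot(nchar(seq) == L)
  list(role = if (nmd) "nmd" else "nonnmd", n = 3L, ex = ex,
       refs = list(ex), design_seq = seq, orf_start = s0,
       orf_end = stop_end, nmd = nmd)
}

arch_event <- function(type, cfg) {
  ii <- function() rint(cfg$intron_len[1], cfg$intron_len[2])
  ee <- function() rint(100L, 200L)
  a <- ee()
  if (type == "SE") {
    i1 <- ii(); b <- ee(); i2 <- ii(); cl <- ee()
    A <- c(0L, a); B <- c(a + i1, a + i1 + b)
    C <- c(B[2] + i2, B[2] + i2 + cl)
    refs <- list(rbind(A, B, C), rbind(A, C))
    key_ts <- c(A[2], B[1], B[2], C[1])
  } else if (type == "MX") {
    i1 <- ii(); b <- ee(); g <- rint(40L, 80L); cl <- ee(); i2 <- ii()
    d <- ee()
    A <- c(0L, a); B <- c(a + i1, a + i1 + b)
    C <- c(B[2] + g, B[2] + g + cl); D <- c(C[2] + i2, C[2] + i2 + d)
    refs <- list(rbind(A, B, D), rbind(A, C, D))
    key_ts <- c(A[2], B[1], B[2], C[1], C[2], D[1])
  } else if (type == "A5") {
    dl <- rint(30L, 80L); i1 <- ii(); b <- ee()
    B <- c(a + dl + i1, a + dl + i1 + b)
    refs <- list(rbind(c(0L, a), B), rbind(c(0L, a + dl), B))
    key_ts <- c(a, a + dl, B[1])
  } else if (type == "A3") {
    i1 <- ii(); dl <- rint(30L, 80L); b <- ee()
    refs <- list(rbind(c(0L, a), c(a + i1 + dl, a + i1 + dl + b)),
                 rbind(c(0L, a), c(a + i1, a + i1 + dl + b)))
    key_ts <- c(a, a + i1, a + i1 + dl)
  } else if (type == "AF") {
    g <- rint(40L, 80L); f2 <- ee(); i1 <- ii(); b <- ee()
    F1 <- c(0L, a); F2 <- c(a + g, a + g + f2)
    B <- c(F2[2] + i1, F2[2] + i1 + b)
    refs <- list(rbind(F1, B), rbind(F2, B))
    key_ts <- c(F1, F2, B[1])
  } else if (type == "AL") {
    i1 <- ii(); l1 <- ee(); g <- rint(40L, 80L); l2 <- ee()
    E <- c(0L, a); L1 <- c(a + i1, a + i1 + l1)
    L2 <- c(L1[2] + g, L1[2] + g + l2)
    refs <- list(rbind(E, L1), rbind(E, L2))
    key_ts <- c(L1, L2, a)
  } else stop("unknown event type ", type)
  rownames(refs[[1]]) <- NULL; rownames(refs[[2]]) <- NULL
  list(role = paste0("event_", type), event_type = type, refs = refs,
       ex = refs[[1]], n = nrow(refs[[1]]), key_ts = key_ts)
}

# map transcription-space structures to the genome
map_pt <- function(x, off, L, strand) {
  if (strand == "+") off + x else off + L - x
}
map_exons <- function(ex, off, L, strand) {
  if (strand == "+") {
    cbind(start = off + ex[, 1], end = off + ex[, 2])
  } else {
    m <- cbind(start = off + L - ex[, 2], end = off + L - ex[, 1])
    m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
}

# genomic event key in the format produced by enumerateEvents()
event_key_genomic <- function(type, key_ts, off, L, strand) {
  p <- function(x) map_pt(x, off, L, strand)
  if (type == "SE") {
    paste(p(key_ts[1]), p(key_ts[2]), p(key_ts[3]), p(key_ts[4]), sep = ",")
  } else if (type == "MX") {
    paste(p(key_ts[1]), p(key_ts[2]), p(key_ts[3]), p(key_ts[4]),
          p(key_ts[5]), p(key_ts[6]), sep = ",")
  } else if (type == "A5") {
    d <- sort(c(p(key_ts[1]), p(key_ts[2])))
    paste(d[1], d[2], p(key_ts[3]), sep = ",")
  } else if (type == "A3") {
    ac <- sort(c(p(key_ts[2]), p(key_ts[3])))
    paste(p(key_ts[1]), ac[1], ac[2], sep = ",")
  } else if (type == "AF" || type == "AL") {
    e1 <- sort(c(p(key_ts[1]), p(key_ts[2])))
    e2 <- sort(c(p(key_ts[3]), p(key_ts[4])))
    if (e2[1] < e1[1]) { tmp <- e1; e1 <- e2; e2 <- tmp }
    paste(e1[1], e1[2], e2[1], e2[2], p(key_ts[5]), sep = ",")
  }
}

# ---- the full deterministic plan ------------------------------------------

sim_plan <- function(cfg) {
  set.seed(cfg$seed)
  blocks <- list()
  addb <- function(b) blocks[[length(blocks) + 1L]] <<- b
  q <- cfg$category_quota
  for (i in seq_len(q[["FSM"]])) addb(list(kind = "gene", role = "fsm"))
  for (i in seq_len(q[["ISM"]])) addb(list(kind = "gene", role = "ism"))
  for (i in seq_len(q[["NIC"]])) addb(list(kind = "gene", role = "nic"))
  for (i in seq_len(q[["NNC"]])) addb(list(kind = "gene", role = "nnc"))
  for (i in seq_len(q[["fusion"]])) addb(list(kind = "fusion"))
  for (i in seq_len(q[["intergenic"]])) addb(list(kind = "desert"))
  for (t in names(cfg$event_quota))
    for (i in seq_len(cfg$event_quota[[t]]))
      addb(list(kind = "gene", role = "event", event_type = t))
  for (i in seq_len(cfg$n_ir_genes)) addb(list(kind = "gene", role = "ir"))
  for (i in seq_len(cfg$n_nmd_genes))
    addb(list(kind = "gene", role = "nmd"))
  for (i in seq_len(cfg$n_nonnmd_genes))
    addb(list(kind = "gene", role = "nonnmd"))
  for (i in seq_len(cfg$n_fragment_multi))
    addb(list(kind = "gene", role = "fragment_multi"))
  for (i in seq_len(cfg$n_fragment_mono))
    addb(list(kind = "gene", role = "fragment_mono"))
  for (i in seq_len(cfg$n_intrapriming))
    addb(list(kind = "gene", role = "intrapriming"))
  blocks <- blocks[sample.int(length(blocks))]

  # accumulators
  ref_rows <- list(); query_rows <- list(); gene_rows <- list()
  truth_rows <- list(); edit_rows <- list(); cage_rows <- list()
  event_truth <- list()
  gene_i <- 0L; tx_i <- 0L
  new_gene <- function() { gene_i <<- gene_i + 1L; sprintf("g%04d", gene_i) }
  new_tx <- function() { tx_i <<- tx_i + 1L; sprintf("q%04d", tx_i) }
  fsm_hosts <- character(0)
  fsm_host_data <- list()
  event_genes <- character(0)
  lnc_pool <- character(0)

  add_ref <- function(gid, tid, exg, chrom, strand) {
    ref_rows[[length(ref_rows) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
      start = exg[, 1], end = exg[, 2], stringsAsFactors = FALSE)
  }
  add_query <- function(tid, gid_attr, exg, chrom, strand) {
    query_rows[[length(query_rows) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = gid_attr, chrom = chrom,
      strand = strand, start = exg[, 1], end = exg[, 2],
      stringsAsFactors = FALSE)
  }
  add_truth <- function(tid, role, category, genes, assoc_tx, ir = FALSE,
                        nmd = NA, has_orf = NA, fragment = FALSE,
                        intrapriming = NA) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      transcript_id = tid, role = role, category = category,
      genes = genes, associated_transcript = assoc_tx, ir = ir, nmd = nmd,
      has_orf = has_orf, fragment = fragment, intrapriming = intrapriming,
      stringsAsFactors = FALSE)
  }
  add_edit <- function(chrom, start, seq) {
    edit_rows[[length(edit_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = start + nchar(seq), seq = seq,
      stringsAsFactors = FALSE)
  }
  balanced20 <- strrep("ACGT", 5L)
  plant_tail <- function(chrom, strand, tts, arich = FALSE) {
    seq <- if (arich) {
      if (strand == "+") strrep("A", 20L) else strrep("T", 20L)
    } else balanced20
    if (strand == "+") add_edit(chrom, tts, seq)
    else add_edit(chrom, tts - 20L, seq)
  }
  add_cage <- function(chrom, tss) {
    jit <- as.integer(round(rnorm(1, 0, cfg$cage_sd)))
    s <- max(tss - cfg$cage_width %/% 2L + jit, 0L)
    cage_rows[[length(cage_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = s, end = s + cfg$cage_width,
      stringsAsFactors = FALSE)
  }

  # sequential placement
  chrom_i <- 1L
  cursor <- 1000L
  place <- function(width) {
    if (cursor + width + 2000L > cfg$chrom_len) {
      chrom_i <<- chrom_i + 1L
      cursor <<- 1000L
    }
    off <- cursor
    cursor <<- cursor + width + rint(cfg$gene_gap[1], cfg$gene_gap[2])
    off
  }

  emit_gene <- function(arch, strand, off, lnc = FALSE) {
    gid <- new_gene()
    L <- max(arch$ex[, 2])
    ref_ids <- character(length(arch$refs))
    for (r in seq_along(arch$refs)) {
      tid <- sprintf("%s.r%d", gid, r)
      ref_ids[r] <- tid
      exg <- map_exons(arch$refs[[r]], off, L, strand)
      add_ref(gid, tid, exg, sprintf("chr%d", chrom_i), strand)
      add_cage(sprintf("chr%d", chrom_i),
               if (strand == "+") exg[1, 1] else exg[nrow(exg), 2])
    }
    if (lnc) lnc_pool <<- c(lnc_pool, gid)
    list(gid = gid, ref_ids = ref_ids, off = off, L = L, strand = strand,
         chrom = sprintf("chr%d", chrom_i))
  }

  for (b in blocks) {
    if (b$kind == "desert") {
      off <- place(5200L)
      strand <- sample(c("+", "-"), 1)
      chrom <- sprintf("chr%d", chrom_i)
      exg <- cbind(start = c(off + 2000L, off + 2500L),
                   end = c(off + 2150L, off + 2650L))
      tid <- new_tx()
      add_query(tid, NA_character_, exg, chrom, strand)
      add_truth(tid, "intergenic", "intergenic", "", "novel",
                intrapriming = FALSE)
      tts <- if (strand == "+") exg[2, 2] else exg[1, 1]
      plant_tail(chrom, strand, tts)
      next
    }
    if (b$kind == "fusion") {
      strand <- sample(c("+", "-"), 1)
      aA <- arch_ordinary("fsm", cfg)
      aB <- arch_ordinary("fsm", cfg)
      LA <- max(aA$ex[, 2]); LB <- max(aB$ex[, 2])
      gap <- rint(cfg$fusion_gap[1], cfg$fusion_gap[2])
      off <- place(LA + gap + LB)
      gA <- emit_gene(aA, strand, off)
      gB_off <- off + LA + gap
      gB <- local({
        # second gene of the pair shares the chromosome cursor
        gid <- new_gene()
        ref_ids <- character(length(aB$refs))
        for (r in seq_along(aB$refs)) {
          tid <- sprintf("%s.r%d", gid, r)
          ref_ids[r] <- tid
          exg <- map_exons(aB$refs[[r]], gB_off, LB, strand)
          add_ref(gid, tid, exg, gA$chrom, strand)
          add_cage(gA$chrom,
                   if (strand == "+") exg[1, 1] else exg[nrow(exg), 2])
        }
        list(gid = gid, ref_ids = ref_ids)
      })
      exq <- rbind(map_exons(aA$refs[[1]], off, LA, strand),
                   map_exons(aB$refs[[1]], gB_off, LB, strand))
      exq <- exq[order(exq[, 1]), , drop = FALSE]
      tid <- new_tx()
      add_query(tid, NA_character_, exq, gA$chrom, strand)
      add_truth(tid, "fusion", "fusion", paste(gA$gid, gB$gid, sep = ";"),
                "novel", intrapriming = FALSE)
      tts <- if (strand == "+") max(exq[, 2]) else min(exq[, 1])
      plant_tail(gA$chrom, strand, tts)
      next
    }
    role <- b$role
    strand <- sample(c("+", "-"), 1)
    arch <- switch(role,
                   nmd = arch_nmd(cfg, TRUE),
                   nonnmd = arch_nmd(cfg, FALSE),
                   event = arch_event(b$event_type, cfg),
                   arch_ordinary(role, cfg))
    L <- max(arch$ex[, 2])
    off <- place(L)
    lnc <- role == "fsm" && runif(1) < cfg$lncrna_fraction
    g <- emit_gene(arch, strand, off, lnc = lnc)
    chrom <- g$chrom
    qtts <- function(exg) if (strand == "+") max(exg[, 2]) else min(exg[, 1])

    if (role == "fsm") {
      r <- rint(1L, length(arch$refs))
      ext <- arch$refs[[r]]
      first_len <- ext[1, 2] - ext[1, 1]
      jit <- rint(0L, min(cfg$tss_jitter_max, first_len - 40L))
      ext[1, 1] <- ext[1, 1] + jit
      exg <- map_exons(ext, off, L, strand)
      tid <- new_tx()
      add_query(tid, g$gid, exg, chrom, strand)
      add_truth(tid, "fsm", "FSM", g$gid, g$ref_ids[r],
                intrapriming = FALSE)
      plant_tail(chrom, strand, qtts(exg))
      fsm_hosts <- c(fsm_hosts, g$gid)
      fsm_host_data[[g$gid]] <- list(off = off, L = L, strand = strand,
                                     chrom = chrom, ex = arch$ex,
                                     n = arch$n)
    } else if (role == "ism") {
      ext <- arch$ex[-1, , drop = FALSE]
      exg <- map_exons(ext, off, L, strand)
      tid <- new_tx()
      add_query(tid, g$gid, exg, chrom, strand)
      add_truth(tid, "ism", "ISM", g$gid, g$ref_ids[1],
                intrapriming = FALSE)
      plant_tail(chrom, strand, qtts(exg))
    } else if (role %in% c("nic", "intrapriming")) {
      ext <- arch$ex[-3, , drop = FALSE]
      exg <- map_exons(ext, off, L, strand)
      tid <- new_tx()
      add_query(tid, g$gid, exg, chrom, strand)
      add_truth(tid, role, "NIC", g$gid, "novel",
                intrapriming = role == "intrapriming")
      plant_tail(chrom, strand, qtts(exg), arich = role == "intrapriming")
    } else if (role == "nnc") {
      ext <- arch$ex
      j <- rint(1L, arch$n - 1L)
      gap_len <- ext[j + 1, 1] - ext[j, 2]
      delta <- rint(3L, min(30L, gap_len - 3L))
      ext[j, 2] <- ext[j, 2] + delta
      exg <- map_exons(ext, off, L, strand)
      tid <- new_tx()
      add_query(tid, g$gid, exg, chrom, strand)
      add_truth(tid, "nnc", "NNC", g$gid, "novel", intrapriming = FALSE)
      plant_tail(chrom, strand, qtts(exg))
    } else if (role == "ir") {
      ext <- rbind(arch$ex[1:2, , drop = FALSE],
                   c(arch$ex[3, 1], arch$ex[4, 2]),
                   arch$ex[-(1:4), , drop = FALSE])
      exg <- map_exons(ext, off, L, strand)
      tid <- new_tx()
      add_query(tid, g$gid, exg, chrom, strand)
      add_truth(tid, "ir", "NIC", g$gid, "novel", ir = TRUE,
                intrapriming = FALSE)
      plant_tail(chrom, strand, qtts(exg))
    } else if (role %in% c("nmd", "nonnmd")) {
      exg <- map_exons(arch$ex, off, L, strand)
      tid <- new_tx()
      add_query(tid, g$gid, exg, chrom, strand)
      add_truth(tid, role, "FSM", g$gid, g$ref_ids[1], nmd = arch$nmd,
                has_orf = TRUE, intrapriming = FALSE)
      plant_tail(chrom, strand, qtts(exg))
      # write the designed spliced sequence into the genome exon by exon
      lens <- arch$ex[, 2] - arch$ex[, 1]
      offs <- c(0L, cumsum(lens))
      for (k in seq_len(nrow(arch$ex))) {
        piece <- substr(arch$design_seq, offs[k] + 1L, offs[k + 1L])
        if (strand == "+") {
          add_edit(chrom, off + arch$ex[k, 1], piece)
        } else {
          rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(piece)))
          add_edit(chrom, off + L - arch$ex[k, 2], rc)
        }
      }
    } else if (role == "event") {
      for (r in 1:2) {
        exg <- map_exons(arch$refs[[r]], off, L, strand)
        tid <- new_tx()
        add_query(tid, g$gid, exg, chrom, strand)
        add_truth(tid, paste0("event_", arch$event_type), "FSM", g$gid,
                  g$ref_ids[r], intrapriming = FALSE)
        plant_tail(chrom, strand, qtts(exg))
      }
      event_genes <- c(event_genes, g$gid)
      event_truth[[length(event_truth) + 1L]] <- data.frame(
        gene_id = g$gid, event_type = arch$event_type,
        key = event_key_genomic(arch$event_type, arch$key_ts, off, L,
                                strand),
        stringsAsFactors = FALSE)
    } else if (role == "fragment_multi") {
      exg <- map_exons(arch$ex, off, L, strand)
      host <- new_tx()
      add_query(host, g$gid, exg, chrom, strand)
      add_truth(host, "fragment_host", "FSM", g$gid, g$ref_ids[1],
                intrapriming = FALSE)
      plant_tail(chrom, strand, qtts(exg))
      f <- rint(1L, arch$n - 2L)
      extf <- arch$ex[-seq_len(f), , drop = FALSE]
      exf <- map_exons(extf, off, L, strand)
      frag <- new_tx()
      add_query(frag, g$gid, exf, chrom, strand)
      add_truth(frag, "fragment", NA_character_, g$gid, NA_character_,
                fragment = TRUE)
    } else if (role == "fragment_mono") {
      exg <- map_exons(arch$ex, off, L, strand)
      host <- new_tx()
      add_query(host, g$gid, exg, chrom, strand)
      add_truth(host, "fragment_host", "FSM", g$gid, g$ref_ids[1],
                intrapriming = FALSE)
      plant_tail(chrom, strand, qtts(exg))
      last <- arch$ex[arch$n, ]
      ts_int <- c(max(last[1] + 5L, L - 120L), L - 20L)
      gs <- sort(c(map_pt(ts_int[1], off, L, strand),
                   map_pt(ts_int[2], off, L, strand)))
      frag <- new_tx()
      add_query(frag, g$gid, cbind(start = gs[1], end = gs[2]), chrom,
                strand)
      add_truth(frag, "fragment", NA_character_, g$gid, NA_character_,
                fragment = TRUE)
    }
  }

  # overlays on distinct FSM host genes
  q <- cfg$category_quota
  need <- q[["antisense"]] + q[["genic_genomic"]] + q[["genic_intron"]]
  hosts <- fsm_hosts[seq_len(need)]
  roles_ov <- c(rep("antisense", q[["antisense"]]),
                rep("genic_genomic", q[["genic_genomic"]]),
                rep("genic_intron", q[["genic_intron"]]))
  for (k in seq_along(roles_ov)) {
    h <- fsm_host_data[[hosts[k]]]
    gex <- map_exons(h$ex, h$off, h$L, h$strand)  # genomic order, full chain
    role <- roles_ov[k]
    tid <- new_tx()
    if (role == "antisense") {
      strand <- if (h$strand == "+") "-" else "+"
      exg <- cbind(start = c(gex[1, 1] + 10L, gex[2, 1] + 10L),
                   end = c(gex[1, 1] + 70L, gex[2, 1] + 70L))
      add_query(tid, NA_character_, exg, h$chrom, strand)
      add_truth(tid, "antisense", "antisense", hosts[k], "novel",
                intrapriming = FALSE)
      tts <- if (strand == "+") exg[2, 2] else exg[1, 1]
      plant_tail(h$chrom, strand, tts)
    } else if (role == "genic_genomic") {
      mid <- (gex[2, 1] + gex[2, 2]) %/% 2L
      ext_into_intron <- min(80L, gex[3, 1] - gex[2, 2] - 40L)
      exg <- cbind(start = mid, end = gex[2, 2] + ext_into_intron)
      add_query(tid, NA_character_, exg, h$chrom, h$strand)
      add_truth(tid, "genic_genomic", "genic_genomic", hosts[k], "novel",
                intrapriming = FALSE)
      tts <- if (h$strand == "+") exg[1, 2] else exg[1, 1]
      plant_tail(h$chrom, h$strand, tts)
    } else {
      l <- gex[2, 2]; r <- gex[3, 1]
      exg <- cbind(start = l + 15L, end = l + 15L + min(100L, r - l - 30L))
      add_query(tid, NA_character_, exg, h$chrom, h$strand)
      add_truth(tid, "genic_intron", "genic_intron", hosts[k], "novel",
                intrapriming = FALSE)
      tts <- if (h$strand == "+") exg[1, 2] else exg[1, 1]
      plant_tail(h$chrom, h$strand, tts)
    }
  }

  list(ref_exons = do.call(rbind, ref_rows),
       query_exons = do.call(rbind, query_rows),
       truth = do.call(rbind, truth_rows),
       edits = do.call(rbind, edit_rows),
       cage = do.call(rbind, cage_rows),
       event_truth = do.call(rbind, event_truth),
       event_genes = event_genes,
       lncrna_genes = lnc_pool,
       n_chroms = chrom_i)
}

apply_edits <- function(genome_chars, edits) {
  # genome_chars: named list of character vectors (one char per base)
  edits <- unique(edits)
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("internal error: overlapping genome edits on ", ch)
    v <- genome_chars[[ch]]
    for (i in seq_len(nrow(e)))
      v[(e$start[i] + 1L):e$end[i]] <- strsplit(e$seq[i], "")[[1]]
    genome_chars[[ch]] <- v
  }
  genome_chars
}

#' Simulate a reference annotation and genome
#'
#' Builds the full deterministic plan for the configured dataset: gene
#' architectures on both strands with shared per-gene splice-site pools,
#' adjacent same-strand gene pairs (fusion substrate), gene deserts
#' (intergenic substrate), a random genome with all planted sequence
#' features (designed ORFs, A-rich tracts, neutral 3' flanks) already
#' applied, and CAGE peaks jittered around every reference TSS.
#'
#' @param config a [simulationConfig()]
#' @return list: `annotation` ([GenomeAnnotation]), `genome`
#'   ([Biostrings::DNAStringSet]), `cage` peaks, `lncrna_genes`, and the
#'   internal `plan` consumed by [simulateQueries()]
#' @export
simulateReference <- function(config) {
  plan <- sim_plan(config)
  ref <- makeTranscriptSet(plan$ref_exons)
  ann <- buildAnnotation(ref, lncrna_genes = plan$lncrna_genes)
  chroms <- sprintf("chr%d", seq_len(plan$n_chroms))
  genome_chars <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE))
  names(genome_chars) <- chroms
  genome_chars <- apply_edits(genome_chars, plan$edits)
  genome <- Biostrings::DNAStringSet(
    vapply(genome_chars, paste, character(1), collapse = ""))
  names(genome) <- chroms
  list(annotation = ann, genome = genome,
       cage = plan$cage, lncrna_genes = plan$lncrna_genes, plan = plan)
}

#' Materialize the query transcript set and its truth labels
#'
#' @param config a [simulationConfig()]
#' @param ref output of [simulateReference()] for the same config
#' @return list: `queries` ([TranscriptSet]), `truth` (per-transcript true
#'   category, associated gene/transcript, IR/NMD/fragment/intrapriming
#'   labels), `event_truth` (per event gene: type and genomic key),
#'   `event_genes`
#' @export
simulateQueries <- function(config, ref) {
  plan <- ref$plan
  queries <- makeTranscriptSet(plan$query_exons)
  verify_plan(queries, ref$annotation, plan)
  list(queries = queries, truth = plan$truth,
       event_truth = plan$event_truth, event_genes = plan$event_genes)
}

# structural sanity of the planted dataset; errors on any ambiguity the
# constructions are supposed to exclude
verify_plan <- function(queries, ann, plan) {
  truth <- plan$truth
  keys <- chainKeys(queries)[truth$transcript_id]
  in_index <- !is.na(keys) & keys %in% names(ann@chainIndex)
  is_fsm <- !is.na(truth$category) & truth$category == "FSM"
  multi <- !is.na(keys)
  if (any(is_fsm & multi & !in_index))
    stop("planted FSM query lost its reference chain: ",
         paste(truth$transcript_id[is_fsm & multi & !in_index],
               collapse = ", "))
  if (any(!is_fsm & in_index))
    stop("planted non-FSM query collides with a reference chain: ",
         paste(truth$transcript_id[!is_fsm & in_index], collapse = ", "))
  invisible(TRUE)
}

#' Simulate negative-binomial count matrices from target TPM levels
#'
#' @param target_tpm numeric matrix (transcripts x groups) of target mean
#'   TPM per group
#' @param group_design named integer vector of samples per group (names must
#'   match `colnames(target_tpm)`)
#' @param depth library size per sample (full-length reads)
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2)
#' @param seed RNG seed
#' @return list: `counts` matrix (samples named `<group>_<i>`), `groups`
#'   named vector sample -> group
#' @export
simulateCountsMatrix <- function(target_tpm, group_design, depth = 2e5,
                                 dispersion = 0.3, seed = 1L) {
  set.seed(seed)
  stopifnot(all(colnames(target_tpm) == names(group_design)))
  samples <- unlist(lapply(names(group_design), function(g)
    paste(g, seq_len(group_design[[g]]), sep = "_")))
  groups <- setNames(rep(names(group_design), group_design), samples)
  counts <- matrix(0, nrow(target_tpm), length(samples),
                   dimnames = list(rownames(target_tpm), samples))
  size <- 1 / dispersion
  for (s in samples) {
    mu <- target_tpm[, groups[[s]]] / 1e6 * depth
    counts[, s] <- rnbinom(length(mu), mu = mu, size = size)
  }
  list(counts = counts, groups = groups)
}

#' Simulate full-length counts with planted isoform switches
#'
#' Background transcripts draw a shared log-normal target TPM for both
#' groups; in each designated DTU gene (taken from the planted AS-event
#' genes, which carry exactly two transcripts) the two transcripts receive
#' swapped group means `dtu_tpm[1]` and `dtu_tpm[2]`.
#'
#' @param config a [simulationConfig()]
#' @param queries output of [simulateQueries()]
#' @return list: `counts`, `groups`, `dtu_truth` (`gene_id`, `is_dtu`,
#'   `tx_up` higher in the first group, `tx_down`)
#' @export
simulateCounts <- function(config, queries) {
  set.seed(config$seed + 1L)
  truth <- queries$truth
  ids <- truth$transcript_id
  gl <- names(config$group_design)
  base <- exp(rnorm(length(ids), config$base_tpm_meanlog,
                    config$base_tpm_sdlog))
  target <- matrix(rep(base, length(gl)), ncol = length(gl),
                   dimnames = list(ids, gl))
  ev <- queries$event_genes
  dtu_genes <- sample(ev, config$n_dtu_genes)
  dtu_truth <- data.frame(gene_id = ev, is_dtu = ev %in% dtu_genes,
                          tx_up = NA_character_, tx_down = NA_character_,
                          stringsAsFactors = FALSE)
  for (g in dtu_genes) {
    tx <- truth$transcript_id[!is.na(truth$genes) & truth$genes == g]
    stopifnot(length(tx) == 2)
    target[tx[1], ] <- c(config$dtu_tpm[1], config$dtu_tpm[2])
    target[tx[2], ] <- c(config$dtu_tpm[2], config$dtu_tpm[1])
    k <- which(dtu_truth$gene_id == g)
    dtu_truth$tx_up[k] <- tx[1]
    dtu_truth$tx_down[k] <- tx[2]
  }
  sim <- simulateCountsMatrix(target, config$group_design,
                              depth = config$depth,
                              dispersion = config$nb_dispersion,
                              seed = config$seed + 2L)
  c(sim, list(dtu_truth = dtu_truth))
}

#' Simulate the complete dataset
#'
#' @param config a [simulationConfig()]
#' @return list combining [simulateReference()], [simulateQueries()] and
#'   [simulateCounts()] outputs
#' @export
simulateDataset <- function(config) {
  ref <- simulateReference(config)
  qs <- simulateQueries(config, ref)
  cts <- simulateCounts(config, qs)
  c(ref[c("annotation", "genome", "cage", "lncrna_genes")], qs, cts,
    list(config = config))
}
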