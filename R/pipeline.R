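# End-to-end orchestration, paper-style summary table and browser-track
# export.

DEFAULT_PALETTE <- c(FSM = "0,0,255", ISM = "0,255,255", NIC = "255,0,0",
                     NNC = "255,165,0", other = "128,128,128")

#' Run the full analysis pipeline
#'
#' Stages: 5'-fragment filtering, structural classification with
#' CAGE/polyA/intrapriming annotation, intrapriming filtering (novel
#' categories only), AS-event enumeration, ORF/coding/NMD prediction, TPM
#' normalization, and (when a two-group design is present) Wilcoxon
#' differential transcript expression and DTU calling. Stages needing the
#' genome are skipped with a notice when no genome is supplied. A structured
#' log (stage, counts in/out) goes to standard error via `message()`.
#'
#' @param queries query [TranscriptSet]
#' @param annotation reference [GenomeAnnotation]
#' @param genome optional [Biostrings::DNAStringSet]
#' @param cage optional CAGE peak table ([readBed()])
#' @param polya_motifs optional motif vector
#' @param counts optional count matrix ([readCounts()])
#' @param groups optional named sample -> group vector
#' @param lncrna_genes optional lncRNA gene-id list
#' @param frag_delta3 3'-end tolerance of the fragment filter (nt)
#' @param intrapriming_rate A-fraction threshold of the intrapriming filter
#' @param coding_cutoff,nmd_min_dist passed to [predictOrfs()]
#' @param dtu_groups length-2 character vector naming the two groups tested
#'   for DTE/DTU (defaults to the first two groups present)
#' @param out_dir optional directory: when given, classification, events,
#'   ORF, expression and DTU tables plus filtered GTF and BED12 track are
#'   written there
#' @return list with all stage outputs
#' @export
runPipeline <- function(queries, annotation, genome = NULL, cage = NULL,
                        polya_motifs = NULL, counts = NULL, groups = NULL,
                        lncrna_genes = NULL, frag_delta3 = 100L,
                        intrapriming_rate = 0.6, coding_cutoff = 0.364,
                        nmd_min_dist = 0L, dtu_groups = NULL,
                        out_dir = NULL) {
  log_stage <- function(...) message("[isoscope] ", ...)
  log_stage("input: ", length(queries), " query transcripts, ",
            nrow(annotation@genes), " reference genes")

  fr <- removeFragments(queries, delta3 = frag_delta3)
  log_stage("fragment filter: removed ",
            length(fr$removed_fragment_ids), ", kept ", length(fr$kept))
  kept <- fr$kept

  cl <- classifyAll(kept, annotation, genome = genome, cage = cage,
                    polya_motifs = polya_motifs,
                    lncrna_genes = lncrna_genes,
                    intrapriming_threshold = intrapriming_rate)
  log_stage("classification: ",
            paste(names(table(cl$category)), table(cl$category),
                  sep = "=", collapse = " "))

  if (!is.null(genome)) {
    ipf <- intraprimingFilter(cl)
    log_stage("intrapriming filter: removed ",
              length(ipf$removed_intrapriming_ids))
  } else {
    log_stage("no genome supplied: intrapriming and ORF stages disabled")
    ipf <- list(kept_ids = cl$transcript_id,
                removed_intrapriming_ids = character(0))
  }
  final <- kept[ipf$kept_ids]
  cl_final <- cl[match(ipf$kept_ids, cl$transcript_id), ]

  grp <- eventGroups(cl_final, final)
  events <- enumerateEvents(final, grp)
  ir <- irAggregate(cl_final)
  log_stage("events: ", nrow(events), " across ",
            length(unique(events$gene_id)), " genes; IR transcripts: ",
            length(ir$ir_transcripts))

  orf <- NULL
  if (!is.null(genome)) {
    orf <- predictOrfs(final, genome, coding_cutoff = coding_cutoff,
                       nmd_min_dist = nmd_min_dist)
    log_stage("ORF: ", sum(orf$has_orf), " with ORF, ",
              sum(orf$nmd_flag), " NMD candidates")
  }

  se <- dte <- dtu <- NULL
  if (!is.null(counts)) {
    common <- intersect(rownames(counts), ipf$kept_ids)
    se <- tpmNormalize(counts[common, , drop = FALSE], groups = groups)
    if (!is.null(groups) && length(unique(groups)) >= 2) {
      gl <- if (is.null(dtu_groups)) unique(unname(groups))[1:2]
      else dtu_groups
      sa <- names(groups)[groups == gl[1]]
      sb <- names(groups)[groups == gl[2]]
      sa <- intersect(sa, colnames(counts))
      sb <- intersect(sb, colnames(counts))
      if (length(sa) >= 2 && length(sb) >= 2) {
        dte <- dteWilcoxon(se, sa, sb)
        tx2gene <- setNames(first_assoc_gene(cl_final),
                            cl_final$transcript_id)
        dtu <- dtuFetalAdult(dte, tx2gene)
        log_stage("DTE/DTU (", gl[1], " vs ", gl[2], "): ",
                  sum(dte$p_value < 0.05, na.rm = TRUE),
                  " transcripts at p<0.05, ", nrow(dtu), " DTU genes")
      }
    }
  }

  summary <- summaryTable(cl_final, orf, ts = final)
  out <- list(fragments = fr, classification = cl_final,
              intrapriming = ipf, transcripts = final, events = events,
              ir = ir, orf = orf, expression = se, dte = dte, dtu = dtu,
              summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) if (!is.null(d))
      write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    wt(cl_final, "classification.tsv")
    writeEvents(events, file.path(out_dir, "events.tsv"))
    wt(orf, "orf.tsv")
    wt(dte, "dte.tsv")
    wt(dtu, "dtu.tsv")
    wt(summary, "summary.tsv")
    writeGtf(final, file.path(out_dir, "transcripts.gtf"),
             annotations = setNames(
               lapply(seq_len(nrow(cl_final)), function(i)
                 c(structural_category = cl_final$category[i])),
               cl_final$transcript_id))
    exportBed12(final, cl_final, file.path(out_dir, "transcripts.bed12"),
                orf = orf)
    log_stage("outputs written to ", out_dir)
  }
  out
}

#' Dataset overview table
#'
#' Counts in the layout of a whole-transcriptome overview: unique genes,
#' annotated vs novel genes, transcript totals, genes with >1 / >10
#' isoforms, coding vs non-coding (when an ORF table is given), known
#' (FSM + ISM) vs novel transcripts, and per-category counts with
#' percentages. Novel genes are the loci of antisense and intergenic
#' transcripts (which do not express an annotated same-strand gene);
#' when the transcript set is supplied they are counted as same-strand
#' overlap clusters, otherwise one locus per transcript.
#'
#' @param classification output of [classifyAll()]
#' @param orf optional output of [predictOrfs()]
#' @param ts optional classified [TranscriptSet], used to cluster
#'   novel-gene transcripts into loci
#' @return `data.frame` with `metric`, `value`, `percent`
#' @export
summaryTable <- function(classification, orf = NULL, ts = NULL) {
  n <- nrow(classification)
  gene <- first_assoc_gene(classification)
  novel_locus <- classification$category %in% c("antisense", "intergenic")
  genes_annot <- unique(gene[!is.na(gene) & !novel_locus])
  n_novel <- if (is.null(ts)) {
    sum(novel_locus)
  } else {
    info <- ts@info[match(classification$transcript_id[novel_locus],
                          ts@info$transcript_id), ]
    cl <- 0L
    for (grp in split(seq_len(nrow(info)), paste(info$chrom, info$strand))) {
      o <- grp[order(info$start[grp])]
      cur_end <- -1L
      for (k in o) {
        if (info$start[k] >= cur_end) cl <- cl + 1L
        cur_end <- max(cur_end, info$end[k])
      }
    }
    cl
  }
  n_genes <- length(genes_annot) + n_novel
  iso <- table(gene[!is.na(gene) & !novel_locus])
  add <- function(metric, value, percent = NA_real_)
    data.frame(metric = metric, value = value, percent = percent,
               stringsAsFactors = FALSE)
  rows <- list(
    add("unique_genes", n_genes),
    add("annotated_genes", length(genes_annot),
        100 * length(genes_annot) / max(n_genes, 1)),
    add("novel_genes", n_novel, 100 * n_novel / max(n_genes, 1)),
    add("transcripts", n),
    add("genes_gt1_isoform", sum(iso > 1),
        100 * sum(iso > 1) / max(n_genes, 1)),
    add("genes_gt10_isoforms", sum(iso > 10),
        100 * sum(iso > 10) / max(n_genes, 1)))
  if (!is.null(orf)) {
    coding <- orf$coding_flag[match(classification$transcript_id,
                                    orf$transcript_id)]
    rows <- c(rows, list(
      add("coding_transcripts", sum(coding, na.rm = TRUE),
          100 * sum(coding, na.rm = TRUE) / n),
      add("noncoding_transcripts", sum(!coding, na.rm = TRUE),
          100 * sum(!coding, na.rm = TRUE) / n)))
  }
  known <- classification$category %in% c("FSM", "ISM")
  rows <- c(rows, list(
    add("known_transcripts", sum(known), 100 * sum(known) / n),
    add("novel_transcripts", sum(!known), 100 * sum(!known) / n)))
  for (cat in CATEGORY_LEVELS) {
    k <- sum(classification$category == cat)
    rows <- c(rows, list(add(paste0("category_", cat), k, 100 * k / n)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a BED12 browser track colored by structural category
#'
#' One BED12 line per transcript with blocks from the exon structure,
#' `itemRgb` from the category palette, and thickStart/thickEnd spanning
#' the ORF's genomic extent when an ORF table is supplied (zero-width at the
#' transcript start otherwise).
#'
#' @param ts a [TranscriptSet]
#' @param classification output of [classifyAll()] covering `ts`
#' @param path output file
#' @param orf optional [predictOrfs()] output
#' @param palette named vector category -> "r,g,b" (entry `other` is the
#'   fallback)
#' @return `path`, invisibly
#' @export
exportBed12 <- function(ts, classification, path, orf = NULL,
                        palette = DEFAULT_PALETTE) {
  info <- ts@info
  if (any(info$n_exons < 1)) stop("transcript without exons")
  cl <- classification[match(info$transcript_id,
                             classification$transcript_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(info))) {
    ex <- ts@exons[[i]]
    col <- unname(palette[cl$category[i]])
    if (is.na(col)) col <- palette[["other"]]
    thick <- c(info$start[i], info$start[i])
    if (!is.null(orf)) {
      k <- match(info$transcript_id[i], orf$transcript_id)
      if (!is.na(k) && isTRUE(orf$has_orf[k])) {
        gpos <- txToGenomic(ts, i, c(orf$orf_start[k], orf$orf_end[k]))
        thick <- sort(gpos)
      }
    }
    writeLines(paste(
      info$chrom[i], info$start[i], info$end[i], info$transcript_id[i],
      0, info$strand[i], thick[1], thick[2], col, nrow(ex),
      paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
      paste0(paste(ex[, 1] - info$start[i], collapse = ","), ","),
      sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BED12 track back into exon intervals
#'
#' @param path BED12 file
#' @return `data.frame` with one row per block: `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, plus per-transcript `itemRgb`
#' @export
readBed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 12)) stop("BED12 line with fewer than 12 fields")
  out <- list()
  for (x in f) {
    start <- as.integer(x[[2]])
    sizes <- as.integer(strsplit(sub(",$", "", x[[11]]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", x[[12]]), ",")[[1]])
    stopifnot(length(sizes) == as.integer(x[[10]]))
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = x[[4]], chrom = x[[1]], strand = x[[6]],
      start = start + offs, end = start + offs + sizes,
      itemRgb = x[[9]], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
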