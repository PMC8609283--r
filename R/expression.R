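# Full-length count normalization, diversity and saturation statistics,
# and threshold-based differential transcript expression/usage.

#' Normalize full-length counts to TPM
#'
#' TPM = count / sample column total * 1e6, so every sample column of the
#' TPM assay sums to one million.
#'
#' @param counts numeric matrix (transcripts x samples), e.g. from
#'   [readCounts()]
#' @param groups optional named character vector mapping sample id to group
#' @return a [SummarizedExperiment::SummarizedExperiment] with assays
#'   `counts` and `tpm` and a `group` column in `colData`
#' @export
tpmNormalize <- function(counts, groups = NULL) {
  if (any(counts < 0)) stop("negative counts")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("zero-total sample column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  tpm <- sweep(counts, 2, tot, "/") * 1e6
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  cd$group <- if (!is.null(groups)) unname(groups[colnames(counts)])
  else NA_character_
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm), colData = cd)
}

#' TPM assay accessor
#' @param se a [SummarizedExperiment::SummarizedExperiment] from
#'   [tpmNormalize()]
#' @export
tpmAssay <- function(se) SummarizedExperiment::assay(se, "tpm")

#' Counts assay accessor
#' @inheritParams tpmAssay
#' @export
countsAssay <- function(se) SummarizedExperiment::assay(se, "counts")

first_assoc_gene <- function(classification) {
  vapply(strsplit(classification$associated_genes, ";", fixed = TRUE),
         function(x) if (length(x) && nzchar(x[1])) x[1] else NA_character_,
         character(1))
}

#' Aggregate transcript counts to gene level
#'
#' Sums member-transcript full-length counts per gene, excluding mono-exonic
#' transcripts when `drop_monoexonic` is on and always excluding fusion
#' transcripts (which have no single gene), then renormalizes the summed
#' counts to TPM.
#'
#' @param se transcript-level experiment from [tpmNormalize()]
#' @param classification output of [classifyAll()] covering all transcripts
#' @param drop_monoexonic drop mono-exonic transcripts before summation
#' @return gene-level [SummarizedExperiment::SummarizedExperiment]
#' @export
geneAggregate <- function(se, classification, drop_monoexonic = TRUE) {
  counts <- countsAssay(se)
  miss <- setdiff(rownames(counts), classification$transcript_id)
  if (length(miss))
    stop("transcript(s) absent from classification: ",
         paste(head(miss, 3), collapse = ", "))
  cl <- classification[match(rownames(counts),
                             classification$transcript_id), ]
  gene <- first_assoc_gene(cl)
  keep <- !is.na(gene) & cl$category != "fusion"
  if (drop_monoexonic) keep <- keep & cl$n_exons > 1
  m <- counts[keep, , drop = FALSE]
  g <- rowsum(m, group = gene[keep])
  grp <- SummarizedExperiment::colData(se)$group
  tpmNormalize(as.matrix(g), groups = setNames(grp, colnames(g)))
}

#' Isoform-diversity statistics
#'
#' Counts detected isoforms per gene and correlates (Pearson) the isoform
#' count with log10 gene length and with exon count, where gene length
#' (genomic span) and exon count come from each gene's representative
#' longest transcript (longest spliced length among detected transcripts).
#' The correlations are also reported restricted to highly expressed genes
#' (log10 mean gene TPM above `hi_expr_log10tpm`).
#'
#' @param classification output of [classifyAll()]
#' @param ts the classified [TranscriptSet]
#' @param gene_tpm optional named numeric vector of mean gene-level TPM
#' @param hi_expr_log10tpm high-expression threshold on log10 TPM
#' @return list: `per_gene` table, correlations (all and highly expressed),
#'   and counts of genes with >1 and >10 isoforms
#' @export
diversityStats <- function(classification, ts, gene_tpm = NULL,
                           hi_expr_log10tpm = 2.5) {
  gene <- first_assoc_gene(classification)
  keep <- !is.na(gene) & classification$category != "fusion"
  cl <- classification[keep, ]
  gene <- gene[keep]
  info <- ts@info[match(cl$transcript_id, ts@info$transcript_id), ]
  per <- do.call(rbind, lapply(split(seq_along(gene), gene), function(ix) {
    rep_ix <- ix[order(-info$length[ix], info$transcript_id[ix])[1]]
    data.frame(gene_id = gene[ix[1]], n_isoforms = length(ix),
               gene_length = info$end[rep_ix] - info$start[rep_ix],
               n_exons = info$n_exons[rep_ix], stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  per$mean_tpm <- if (!is.null(gene_tpm)) unname(gene_tpm[per$gene_id])
  else NA_real_
  safe_cor <- function(x, y) {
    ok <- complete.cases(x, y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  hi <- !is.na(per$mean_tpm) & per$mean_tpm > 0 &
    log10(per$mean_tpm) > hi_expr_log10tpm
  list(per_gene = per,
       cor_length = safe_cor(per$n_isoforms, log10(per$gene_length)),
       cor_exons = safe_cor(per$n_isoforms, per$n_exons),
       cor_length_hi = safe_cor(per$n_isoforms[hi],
                                log10(per$gene_length[hi])),
       cor_exons_hi = safe_cor(per$n_isoforms[hi], per$n_exons[hi]),
       genes_gt1 = sum(per$n_isoforms > 1),
       genes_gt10 = sum(per$n_isoforms > 10))
}

#' Rarefaction of transcript (and gene) discovery
#'
#' Subsamples the read-to-transcript assignment vector without replacement
#' `reps` times at each depth and reports the mean and SD of the number of
#' distinct transcripts (and genes, when a mapping is given).
#'
#' @param assignments character vector, one transcript id per read
#' @param depths integer vector of subsampling depths (<= total reads)
#' @param reps replicates per depth
#' @param seed RNG seed
#' @param gene_of optional named vector transcript id -> gene id
#' @return `data.frame`: `depth`, `mean_transcripts`, `sd_transcripts`,
#'   optionally `mean_genes`, `sd_genes`, and `reps`
#' @export
rarefactionCurve <- function(assignments, depths, reps = 30L, seed = 1L,
                             gene_of = NULL) {
  N <- length(assignments)
  if (any(depths > N)) stop("depth exceeds total number of reads")
  set.seed(seed)
  f <- factor(assignments)
  code <- as.integer(f)
  gcode <- if (!is.null(gene_of))
    as.integer(factor(unname(gene_of[levels(f)])))
  out <- data.frame(depth = as.integer(depths),
                    mean_transcripts = NA_real_, sd_transcripts = NA_real_,
                    mean_genes = NA_real_, sd_genes = NA_real_,
                    reps = as.integer(reps))
  for (k in seq_along(depths)) {
    d <- depths[k]
    ut <- numeric(reps); ug <- numeric(reps)
    for (r in seq_len(reps)) {
      if (d == 0) { ut[r] <- 0; ug[r] <- 0; next }
      sub <- code[sample.int(N, d)]
      seen <- unique(sub)
      ut[r] <- length(seen)
      if (!is.null(gcode)) ug[r] <- length(unique(gcode[seen]))
    }
    out$mean_transcripts[k] <- mean(ut)
    out$sd_transcripts[k] <- sd(ut)
    if (!is.null(gcode)) {
      out$mean_genes[k] <- mean(ug)
      out$sd_genes[k] <- sd(ug)
    }
  }
  out
}

#' Expected number of distinct features at a subsampling depth
#'
#' Closed-form hypergeometric expectation
#' `sum_i (1 - choose(N - n_i, d) / choose(N, d))` for feature read counts
#' `n_i` with `N = sum(n_i)`.
#'
#' @param feature_counts integer vector of per-feature read counts
#' @param depth subsampling depth
#' @return numeric expectation
#' @export
rarefactionExpected <- function(feature_counts, depth) {
  n <- feature_counts[feature_counts > 0]
  N <- sum(n)
  if (depth > N) stop("depth exceeds total reads")
  sum(1 - exp(lchoose(N - n, depth) - lchoose(N, depth)))
}

#' Per-transcript Wilcoxon rank-sum differential expression
#'
#' Two-sided rank-sum test on TPM between two sample groups: exact when the
#' combined sample size is <= 20 and the values carry no ties, otherwise the
#' mid-rank normal approximation with continuity correction.
#'
#' @param se experiment from [tpmNormalize()]
#' @param samples_a,samples_b sample ids of the two groups (>= 2 each)
#' @return `data.frame`: `transcript_id`, group means, `delta`
#'   (mean A - mean B), `p_value`, `direction` (+1 when A > B), `exact`
#' @export
dteWilcoxon <- function(se, samples_a, samples_b) {
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each group needs at least two samples")
  tpm <- tpmAssay(se)
  miss <- setdiff(c(samples_a, samples_b), colnames(tpm))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  n <- nrow(tpm)
  out <- data.frame(transcript_id = rownames(tpm),
                    mean_a = NA_real_, mean_b = NA_real_, delta = NA_real_,
                    p_value = NA_real_, direction = NA_integer_,
                    exact = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    x <- tpm[i, samples_a]; y <- tpm[i, samples_b]
    use_exact <- (length(x) + length(y)) <= 20 &&
      !anyDuplicated(c(x, y))
    p <- if (length(unique(c(x, y))) == 1) 1  # degenerate: symmetric null
    else suppressWarnings(stats::wilcox.test(
      x, y, alternative = "two.sided", exact = use_exact,
      correct = TRUE))$p.value
    out$mean_a[i] <- mean(x); out$mean_b[i] <- mean(y)
    out$delta[i] <- out$mean_a[i] - out$mean_b[i]
    out$p_value[i] <- p
    out$direction[i] <- sign(out$delta[i])
    out$exact[i] <- use_exact
  }
  out
}

#' Differential transcript usage between two conditions (fetal/adult rule)
#'
#' A gene is called when at least two of its transcripts show exclusive
#' (opposite-direction) significant differential expression, each with an
#' absolute mean-TPM difference above `min_delta_tpm`.
#'
#' @param dte output of [dteWilcoxon()]
#' @param tx2gene named vector transcript id -> gene id
#' @param alpha significance threshold (default 0.05)
#' @param min_delta_tpm TPM-difference gate (strict `>`, default 20)
#' @return `data.frame` of called genes with the supporting transcripts and
#'   numbers; zero rows when nothing is called
#' @export
dtuFetalAdult <- function(dte, tx2gene, alpha = 0.05, min_delta_tpm = 20) {
  gene <- unname(tx2gene[dte$transcript_id])
  sig_up <- !is.na(dte$p_value) & dte$p_value < alpha &
    dte$delta > min_delta_tpm
  sig_dn <- !is.na(dte$p_value) & dte$p_value < alpha &
    dte$delta < -min_delta_tpm
  out <- list()
  for (g in unique(gene[!is.na(gene)])) {
    ix <- which(gene == g)
    up <- ix[sig_up[ix]]; dn <- ix[sig_dn[ix]]
    if (length(up) && length(dn)) {
      out[[g]] <- data.frame(
        gene_id = g,
        rule = "fetal_adult",
        up_transcripts = paste(dte$transcript_id[up], collapse = ";"),
        down_transcripts = paste(dte$transcript_id[dn], collapse = ";"),
        max_up_delta = max(dte$delta[up]),
        max_down_delta = min(dte$delta[dn]),
        min_p = min(dte$p_value[c(up, dn)]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), rule = character(),
                      up_transcripts = character(),
                      down_transcripts = character(),
                      max_up_delta = numeric(), max_down_delta = numeric(),
                      min_p = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id), , drop = FALSE]
}

#' Threshold-based differential transcript usage between two regions
#'
#' With too few samples for a rank test, a transcript is flagged when the
#' pseudocount-stabilized fold change of mean TPM is at least `min_fc` (in
#' either direction) and the absolute mean difference exceeds `min_delta`;
#' a gene shows DTU when at least two transcripts are flagged in opposite
#' directions.
#'
#' @param se experiment from [tpmNormalize()]
#' @param samples_a,samples_b sample ids of the two regions (>= 1 each)
#' @param tx2gene named vector transcript id -> gene id
#' @param min_fc minimum fold change (default 4)
#' @param min_delta minimum absolute TPM difference (strict `>`, default 20)
#' @param pseudocount TPM pseudocount for the fold change (default 1)
#' @return list: `transcripts` (per-transcript flags) and `genes`
#'   (gene-level DTU calls)
#' @export
dtuRegionPair <- function(se, samples_a, samples_b, tx2gene,
                          min_fc = 4, min_delta = 20, pseudocount = 1) {
  tpm <- tpmAssay(se)
  ma <- rowMeans(tpm[, samples_a, drop = FALSE])
  mb <- rowMeans(tpm[, samples_b, drop = FALSE])
  fc <- (ma + pseudocount) / (mb + pseudocount)
  flagged <- (fc >= min_fc | fc <= 1 / min_fc) & abs(ma - mb) > min_delta
  tx <- data.frame(transcript_id = rownames(tpm), mean_a = ma, mean_b = mb,
                   fold_change = fc, delta = ma - mb, flagged = flagged,
                   direction = ifelse(ma >= mb, 1L, -1L),
                   row.names = NULL, stringsAsFactors = FALSE)
  gene <- unname(tx2gene[tx$transcript_id])
  calls <- list()
  for (g in unique(gene[!is.na(gene)])) {
    ix <- which(gene == g & tx$flagged)
    if (length(ix) >= 2 && length(unique(tx$direction[ix])) == 2) {
      calls[[g]] <- data.frame(
        gene_id = g, rule = "region_pair",
        up_transcripts = paste(tx$transcript_id[ix][tx$direction[ix] == 1],
                               collapse = ";"),
        down_transcripts = paste(tx$transcript_id[ix][tx$direction[ix] == -1],
                                 collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(calls)) do.call(rbind, calls)
  else data.frame(gene_id = character(), rule = character(),
                  up_transcripts = character(),
                  down_transcripts = character(), stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  list(transcripts = tx, genes = genes[order(genes$gene_id), , drop = FALSE])
}

#' Group-specific transcripts
#'
#' `detection` mode: a transcript is specific to a group when it has a
#' positive count in every sample of that group and zero counts in all other
#' samples. `tpm_threshold` mode: mean TPM above `tpm_min` in exactly one
#' group and at or below it in all others.
#'
#' @param se experiment from [tpmNormalize()]
#' @param groups named character vector sample id -> group
#' @param mode `"detection"` or `"tpm_threshold"`
#' @param tpm_min TPM threshold for `tpm_threshold` mode (strict `>`)
#' @return named list, one transcript-id vector per group
#' @export
groupSpecificTranscripts <- function(se, groups,
                                     mode = c("detection", "tpm_threshold"),
                                     tpm_min = 20) {
  mode <- match.arg(mode)
  counts <- countsAssay(se)
  tpm <- tpmAssay(se)
  gl <- unique(unname(groups[colnames(counts)]))
  out <- setNames(vector("list", length(gl)), gl)
  for (g in gl) {
    inG <- colnames(counts)[unname(groups[colnames(counts)]) == g]
    outG <- setdiff(colnames(counts), inG)
    if (mode == "detection") {
      ok <- rowSums(counts[, inG, drop = FALSE] > 0) == length(inG) &
        rowSums(counts[, outG, drop = FALSE] > 0) == 0
    } else {
      mg <- rowMeans(tpm[, inG, drop = FALSE])
      others <- vapply(setdiff(gl, g), function(h)
        rowMeans(tpm[, colnames(counts)[unname(groups[colnames(counts)]) ==
                                          h], drop = FALSE]),
        numeric(nrow(tpm)))
      ok <- mg > tpm_min & apply(others <= tpm_min, 1, all)
    }
    out[[g]] <- rownames(counts)[ok]
  }
  out
}

#' Compare per-gene isoform counts between two datasets via a homolog map
#'
#' Joins the two count vectors through a one-to-one homolog map (non-unique
#' mappings are dropped with a message), reports the Pearson correlation,
#' and ranks genes by absolute (`|a - b|`) and relative
#' (`max(a,b) / max(min(a,b), 1)`) difference.
#'
#' @param counts_a named numeric vector: isoform count per gene, dataset A
#' @param counts_b named numeric vector for dataset B
#' @param homologs `data.frame` with columns `a` and `b` (gene ids in the
#'   two datasets); defaults to the identity map over shared names
#' @return list: `table`, `correlation`, `top_absolute`, `top_relative`
#' @export
crossDatasetCompare <- function(counts_a, counts_b, homologs = NULL) {
  if (is.null(homologs)) {
    shared <- intersect(names(counts_a), names(counts_b))
    homologs <- data.frame(a = shared, b = shared,
                           stringsAsFactors = FALSE)
  }
  dup <- homologs$a %in% homologs$a[duplicated(homologs$a)] |
    homologs$b %in% homologs$b[duplicated(homologs$b)]
  if (any(dup)) {
    message("dropping ", sum(dup), " non-unique homolog mapping(s)")
    homologs <- homologs[!dup, , drop = FALSE]
  }
  keep <- homologs$a %in% names(counts_a) & homologs$b %in% names(counts_b)
  homologs <- homologs[keep, , drop = FALSE]
  if (nrow(homologs) == 0) stop("no shared genes after homolog mapping")
  a <- unname(counts_a[homologs$a])
  b <- unname(counts_b[homologs$b])
  tab <- data.frame(gene_a = homologs$a, gene_b = homologs$b,
                    n_isoforms_a = a, n_isoforms_b = b,
                    abs_diff = abs(a - b),
                    rel_diff = pmax(a, b) / pmax(pmin(a, b), 1),
                    stringsAsFactors = FALSE)
  corr <- if (nrow(tab) >= 3 && sd(a) > 0 && sd(b) > 0) stats::cor(a, b)
  else NA_real_
  list(table = tab, correlation = corr,
       top_absolute = tab[order(-tab$abs_diff, tab$gene_a), ],
       top_relative = tab[order(-tab$rel_diff, tab$gene_a), ])
}
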