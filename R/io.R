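# Readers/writers for the standard formats the pipeline touches. GTF is
# 1-based inclusive on disk; everything internal is 0-based half-open, and the
# conversion happens only here.

parse_gtf_attrs <- function(attr) {
  # returns named character vector; values are unquoted and unescaped
  m <- gregexpr('(\\w+) "((?:[^"\\\\]|\\\\.)*)"', attr, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  pieces <- regmatches(attr, gregexpr('(\\w+) "((?:[^"\\\\]|\\\\.)*)"', attr,
                                      perl = TRUE))[[1]]
  keys <- sub(' .*$', '', pieces)
  vals <- sub('^\\w+ "', '', pieces)
  vals <- sub('"$', '', vals)
  vals <- gsub('\\\\(["\\\\])', '\\1', vals)
  setNames(vals, keys)
}

format_gtf_attrs <- function(named) {
  vals <- gsub('(["\\\\])', '\\\\\\1', as.character(named))
  paste0(names(named), ' "', vals, '";', collapse = " ")
}

#' Read a GTF file of transcript models
#'
#' Coordinates are converted from the on-disk 1-based inclusive convention to
#' the internal 0-based half-open convention. Exon features must carry
#' `gene_id` and `transcript_id` attributes. For `kind = "reference"` the
#' per-gene splice-site and junction-chain indexes are built; explicit `gene`
#' feature lines are optional (gene extents default to the union span of
#' each gene's transcripts). Genes whose `gene_type` attribute equals
#' `"lncRNA"` are flagged as lncRNA unless an explicit list is supplied to
#' [classifyAll()].
#'
#' @param path GTF file path
#' @param kind `"query"` returns a [TranscriptSet]; `"reference"` returns a
#'   [GenomeAnnotation]
#' @return a [TranscriptSet] or [GenomeAnnotation]
#' @export
readGtf <- function(path, kind = c("query", "reference")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    ts <- makeTranscriptSet(data.frame(transcript_id = character(),
                                       gene_id = character(),
                                       chrom = character(),
                                       strand = character(),
                                       start = integer(), end = integer()))
    if (kind == "query") return(ts)
    return(buildAnnotation(ts,
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop("malformed GTF line ", lnum[which(nf < 9)[1]],
         ": expected 9 tab-separated fields")
  feat <- vapply(fields, `[[`, character(1), 3L)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  strand <- vapply(fields, `[[`, character(1), 7L)
  attrs <- vapply(fields, `[[`, character(1), 9L)
  if (anyNA(start1) || anyNA(end1))
    stop("malformed GTF line ", lnum[which(is.na(start1) | is.na(end1))[1]],
         ": non-numeric coordinates")
  if (any(end1 < start1))
    stop("validation error at line ", lnum[which(end1 < start1)[1]],
         ": end < start")

  is_exon <- feat == "exon"
  al <- lapply(attrs[is_exon], parse_gtf_attrs)
  tid <- vapply(al, function(a) a[["transcript_id"]], character(1))
  gid <- vapply(al, function(a)
    if ("gene_id" %in% names(a)) a[["gene_id"]] else NA_character_,
    character(1))
  exon_df <- data.frame(transcript_id = tid, gene_id = gid,
                        chrom = chrom[is_exon], strand = strand[is_exon],
                        start = start1[is_exon] - 1L, end = end1[is_exon],
                        stringsAsFactors = FALSE)
  ts <- makeTranscriptSet(exon_df)

  # carry non-core transcript-level attributes (first exon wins)
  extra <- lapply(split(al, factor(tid, levels = names(ts))), function(x) {
    a <- x[[1]]
    a[setdiff(names(a), c("gene_id", "transcript_id"))]
  })
  attr(ts, "attributes") <- extra

  if (kind == "query") return(ts)

  is_gene <- feat == "gene"
  genes <- NULL
  lnc <- character(0)
  gene_attr <- lapply(attrs[is_gene], parse_gtf_attrs)
  if (any(is_gene)) {
    g_id <- vapply(gene_attr, function(a) a[["gene_id"]], character(1))
    genes <- data.frame(gene_id = g_id, chrom = chrom[is_gene],
                        strand = strand[is_gene],
                        start = start1[is_gene] - 1L, end = end1[is_gene],
                        stringsAsFactors = FALSE)
    gtype <- vapply(gene_attr, function(a)
      if ("gene_type" %in% names(a)) a[["gene_type"]] else NA_character_,
      character(1))
    lnc <- g_id[!is.na(gtype) & gtype == "lncRNA"]
    # genes with no explicit feature line fall back to transcript union span
    missing <- setdiff(unique(ts@info$gene_id), genes$gene_id)
    if (length(missing)) {
      info <- ts@info[ts@info$gene_id %in% missing, ]
      add <- do.call(rbind, lapply(split(info, info$gene_id), function(d)
        data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                   strand = d$strand[1], start = min(d$start),
                   end = max(d$end), stringsAsFactors = FALSE)))
      genes <- rbind(genes, add)
    }
  }
  buildAnnotation(ts, genes = genes, lncrna_genes = lnc)
}

#' Write transcript models as GENCODE-dialect GTF
#'
#' Emits one `transcript` feature and one `exon` feature per exon, 1-based
#' inclusive. Attribute values containing quotes or backslashes are escaped so
#' the file re-parses losslessly.
#'
#' @param ts a [TranscriptSet]
#' @param path output file
#' @param annotations optional named list (by transcript id) of named
#'   character vectors of extra attributes (e.g. structural category)
#' @param source source column value
#' @return `path`, invisibly
#' @export
writeGtf <- function(ts, path, annotations = NULL, source = "isoscope") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  info <- ts@info
  for (i in seq_len(nrow(info))) {
    id <- info$transcript_id[i]
    core <- c(gene_id = if (is.na(info$gene_id[i])) id else info$gene_id[i],
              transcript_id = id)
    extra <- if (!is.null(annotations) && id %in% names(annotations))
      annotations[[id]] else character(0)
    at <- format_gtf_attrs(c(core, extra))
    writeLines(paste(info$chrom[i], source, "transcript",
                     info$start[i] + 1L, info$end[i], ".", info$strand[i],
                     ".", at, sep = "\t"), con)
    ex <- ts@exons[[i]]
    for (k in seq_len(nrow(ex))) {
      writeLines(paste(info$chrom[i], source, "exon",
                       ex[k, 1] + 1L, ex[k, 2], ".", info$strand[i], ".",
                       at, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a reference annotation (gene + transcript + exon features) as GTF
#'
#' @param ann a [GenomeAnnotation]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeAnnotationGtf <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  g <- ann@genes
  info <- ann@transcripts@info
  for (i in seq_len(nrow(g))) {
    at <- format_gtf_attrs(c(
      gene_id = g$gene_id[i],
      gene_type = if (g$lncrna[i]) "lncRNA" else "protein_coding"))
    writeLines(paste(g$chrom[i], "isoscope", "gene", g$start[i] + 1L,
                     g$end[i], ".", g$strand[i], ".", at, sep = "\t"), con)
    for (tid in ann@geneTx[[g$gene_id[i]]]) {
      k <- match(tid, info$transcript_id)
      at2 <- format_gtf_attrs(c(gene_id = g$gene_id[i],
                                transcript_id = tid))
      writeLines(paste(info$chrom[k], "isoscope", "transcript",
                       info$start[k] + 1L, info$end[k], ".",
                       info$strand[k], ".", at2, sep = "\t"), con)
      ex <- ann@transcripts@exons[[k]]
      for (e in seq_len(nrow(ex)))
        writeLines(paste(info$chrom[k], "isoscope", "exon", ex[e, 1] + 1L,
                         ex[e, 2], ".", info$strand[k], ".", at2,
                         sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a full-length read-count table
#'
#' Tab-separated, first column transcript ids, remaining columns one per
#' sample with a header row of sample ids.
#'
#' @param path TSV path
#' @return numeric matrix, rows = transcripts, columns = samples
#' @export
readCounts <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- d[[1]]
  if (anyDuplicated(ids)) stop("duplicate transcript row in counts table")
  m <- as.matrix(d[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample id in counts table")
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric count value")
  if (any(m < 0)) stop("negative count value")
  rownames(m) <- ids
  m
}

#' Write a count matrix as TSV
#' @param counts numeric matrix with transcript-id rownames
#' @param path output file
#' @export
writeCounts <- function(counts, path) {
  d <- data.frame(transcript_id = rownames(counts), counts,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals (e.g. CAGE peaks)
#'
#' BED is already 0-based half-open, so no coordinate conversion occurs.
#'
#' @param path BED path (>= 3 columns; strand read from column 6 if present)
#' @return `data.frame`: `chrom`, `start`, `end`, `strand`
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3)) stop("BED line with fewer than 3 fields")
  data.frame(
    chrom = vapply(f, `[[`, character(1), 1L),
    start = as.integer(vapply(f, `[[`, character(1), 2L)),
    end = as.integer(vapply(f, `[[`, character(1), 3L)),
    strand = vapply(f, function(x) if (length(x) >= 6) x[[6]] else "*",
                    character(1)),
    stringsAsFactors = FALSE)
}

#' Read a genome FASTA into a DNAStringSet keyed by sequence name
#' @param path FASTA path
#' @return named [Biostrings::DNAStringSet]
#' @export
readFasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("duplicate FASTA headers")
  g
}

#' Read a plain-text polyA motif list (one uppercase DNA motif per line)
#' @param path file path
#' @return character vector of motifs
#' @export
readPolyaMotifs <- function(path) {
  m <- readLines(path)
  m <- m[nzchar(m)]
  if (any(!grepl("^[ACGT]+$", m)))
    stop("polyA motifs must be non-empty uppercase DNA (A/C/G/T)")
  m
}

#' Read a sample-group table (sample_id<TAB>group)
#' @param path TSV path (no header required; 2 columns)
#' @return named character vector mapping sample id to group
#' @export
readGroups <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("group file needs two columns: sample_id, group")
  setNames(as.character(d[[2]]), as.character(d[[1]]))
}

#' Extract a genomic subsequence with bounds checking
#'
#' @param genome named [Biostrings::DNAStringSet]
#' @param chrom chromosome name
#' @param start,end 0-based half-open coordinates
#' @param strand if `"-"`, the reverse complement is returned
#' @return character DNA string
#' @export
genomeSubseq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("chromosome ", chrom,
                                      " absent from genome")
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop("sequence lookup [", start, ",", end, ") outside bounds of ",
         chrom, " (length ", len, ")")
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
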