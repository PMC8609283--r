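# Constructors and accessors for transcript models. All genomic coordinates
# are 0-based half-open; strand is "+" or "-".

chain_key <- function(chrom, strand, introns) {
  if (is.null(introns) || nrow(introns) == 0) return(NA_character_)
  paste0(chrom, ":", strand, ":",
         paste(introns[, 1], introns[, 2], sep = "-", collapse = ";"))
}

#' Build a TranscriptSet from a per-exon table
#'
#' @param exon_df `data.frame` with one row per exon: `transcript_id`,
#'   `gene_id` (may be `NA`), `chrom`, `strand`, `start`, `end` (0-based
#'   half-open).
#' @return a [TranscriptSet]
#' @examples
#' ts <- makeTranscriptSet(data.frame(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
#'   start = c(0, 200), end = c(100, 300)))
#' txJunctions(ts, "t1")
#' @export
makeTranscriptSet <- function(exon_df) {
  stopifnot(all(c("transcript_id", "chrom", "strand", "start", "end") %in%
                names(exon_df)))
  if (!"gene_id" %in% names(exon_df))
    exon_df$gene_id <- rep(NA_character_, nrow(exon_df))
  if (nrow(exon_df) == 0) {
    return(new("TranscriptSet",
               info = data.frame(transcript_id = character(),
                                 gene_id = character(), chrom = character(),
                                 strand = character(), start = integer(),
                                 end = integer(), n_exons = integer(),
                                 length = integer(),
                                 stringsAsFactors = FALSE),
               exons = list(), introns = list(), chainKey = character()))
  }
  if (any(exon_df$end <= exon_df$start))
    stop("exon with end <= start")
  ids <- unique(exon_df$transcript_id)
  sp <- split(exon_df, factor(exon_df$transcript_id, levels = ids))
  exons <- vector("list", length(ids))
  introns <- vector("list", length(ids))
  info <- data.frame(transcript_id = ids,
                     gene_id = NA_character_, chrom = NA_character_,
                     strand = NA_character_, start = NA_integer_,
                     end = NA_integer_, n_exons = NA_integer_,
                     length = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    d <- sp[[k]]
    if (length(unique(d$chrom)) > 1L || length(unique(d$strand)) > 1L)
      stop("transcript ", ids[k], " has exons on multiple chromosomes/strands")
    o <- order(d$start)
    ex <- cbind(start = as.integer(d$start[o]), end = as.integer(d$end[o]))
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
      stop("transcript ", ids[k], " has overlapping exons")
    exons[[k]] <- ex
    n <- nrow(ex)
    introns[[k]] <- if (n > 1)
      cbind(left = ex[-n, 2], right = ex[-1, 1])
    else
      cbind(left = integer(0), right = integer(0))
    info$gene_id[k] <- d$gene_id[1]
    info$chrom[k] <- d$chrom[1]
    info$strand[k] <- d$strand[1]
    info$start[k] <- ex[1, 1]
    info$end[k] <- ex[n, 2]
    info$n_exons[k] <- n
    info$length[k] <- sum(ex[, 2] - ex[, 1])
  }
  names(exons) <- ids
  names(introns) <- ids
  keys <- vapply(seq_along(ids), function(k)
    chain_key(info$chrom[k], info$strand[k], introns[[k]]), character(1))
  new("TranscriptSet", info = info, exons = exons, introns = introns,
      chainKey = keys)
}

#' Per-transcript metadata table
#' @param ts a [TranscriptSet]
#' @return `data.frame` with one row per transcript
#' @export
txInfo <- function(ts) ts@info

#' Exons of one transcript
#' @param ts a [TranscriptSet]
#' @param id transcript id or index
#' @return integer matrix (columns `start`, `end`), ascending genomic order
#' @export
txExons <- function(ts, id) {
  if (is.character(id)) ts@exons[[match(id, ts@info$transcript_id)]]
  else ts@exons[[id]]
}

#' Splice junctions of one transcript in transcription order
#'
#' The donor of a junction is the intron boundary adjacent to the upstream
#' exon on the transcript's strand; on the minus strand the transcription-order
#' junction list is therefore the reverse of the genomic-order intron list,
#' with donor and acceptor swapped.
#'
#' @inheritParams txExons
#' @return integer matrix with columns `donor`, `acceptor`, one row per
#'   junction in transcription order (0 rows for mono-exonic transcripts)
#' @export
txJunctions <- function(ts, id) {
  i <- if (is.character(id)) match(id, ts@info$transcript_id) else id
  intr <- ts@introns[[i]]
  if (ts@info$strand[i] == "+") {
    cbind(donor = intr[, 1], acceptor = intr[, 2])
  } else {
    n <- nrow(intr)
    cbind(donor = rev(intr[, 2]), acceptor = rev(intr[, 1]))
  }
}

#' Junction-chain keys
#' @param ts a [TranscriptSet]
#' @return character vector, `NA` for mono-exonic transcripts
#' @export
chainKeys <- function(ts) setNames(ts@chainKey, ts@info$transcript_id)

# 5' end coordinate (half-open convention: start on "+", end on "-")
txTss <- function(info) ifelse(info$strand == "+", info$start, info$end)
# 3' end coordinate
txTts <- function(info) ifelse(info$strand == "+", info$end, info$start)

#' Combine transcript sets
#' @param x,... `TranscriptSet` objects
#' @export
setMethod("c", "TranscriptSet", function(x, ...) {
  all <- c(list(x), list(...))
  info <- do.call(rbind, lapply(all, function(t) t@info))
  rownames(info) <- NULL
  new("TranscriptSet",
      info = info,
      exons = do.call(c, lapply(all, function(t) t@exons)),
      introns = do.call(c, lapply(all, function(t) t@introns)),
      chainKey = do.call(c, lapply(all, function(t) t@chainKey)))
})

#' Build a GenomeAnnotation from reference transcripts
#'
#' Gene extents default to the union span of each gene's transcripts when no
#' explicit gene table is supplied.
#'
#' @param ts a [TranscriptSet] of reference transcripts with `gene_id` set
#' @param genes optional `data.frame` (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`) of gene extents
#' @param lncrna_genes character vector of gene ids flagged as lncRNA
#' @return a [GenomeAnnotation]
#' @export
buildAnnotation <- function(ts, genes = NULL, lncrna_genes = character()) {
  info <- ts@info
  if (anyNA(info$gene_id))
    stop("reference transcripts must carry gene_id")
  gid <- unique(info$gene_id)
  byg <- split(seq_len(nrow(info)), factor(info$gene_id, levels = gid))
  if (is.null(genes)) {
    genes <- data.frame(
      gene_id = gid,
      chrom = vapply(byg, function(i) info$chrom[i[1]], character(1)),
      strand = vapply(byg, function(i) info$strand[i[1]], character(1)),
      start = vapply(byg, function(i) min(info$start[i]), integer(1)),
      end = vapply(byg, function(i) max(info$end[i]), integer(1)),
      stringsAsFactors = FALSE)
  } else {
    genes <- genes[, c("gene_id", "chrom", "strand", "start", "end")]
    extra <- setdiff(gid, genes$gene_id)
    if (length(extra))
      stop("transcripts reference unknown gene(s): ",
           paste(head(extra, 3), collapse = ", "))
  }
  genes$lncrna <- genes$gene_id %in% lncrna_genes
  for (g in gid) {
    i <- byg[[g]]
    if (length(unique(info$chrom[i])) > 1 ||
        length(unique(info$strand[i])) > 1)
      stop("gene ", g, " has transcripts on multiple chromosomes/strands")
  }
  site <- lapply(byg, function(i) {
    don <- integer(0); acc <- integer(0)
    for (k in i) {
      intr <- ts@introns[[k]]
      if (nrow(intr) == 0) next
      if (info$strand[k] == "+") {
        don <- c(don, intr[, 1]); acc <- c(acc, intr[, 2])
      } else {
        don <- c(don, intr[, 2]); acc <- c(acc, intr[, 1])
      }
    }
    list(donors = sort(unique(don)), acceptors = sort(unique(acc)))
  })
  names(site) <- gid
  intron_idx <- lapply(byg, function(i) {
    m <- do.call(rbind, ts@introns[i])
    if (is.null(m) || nrow(m) == 0)
      return(cbind(left = integer(0), right = integer(0)))
    unique(m)
  })
  names(intron_idx) <- gid
  multi <- which(!is.na(ts@chainKey))
  chain <- split(info$transcript_id[multi], ts@chainKey[multi])
  genetx <- lapply(byg, function(i) info$transcript_id[i])
  names(genetx) <- gid
  new("GenomeAnnotation", transcripts = ts, genes = genes,
      siteIndex = site, chainIndex = chain, intronIndex = intron_idx,
      geneTx = genetx)
}

#' Reference genes table
#' @param ann a [GenomeAnnotation]
#' @export
refGenes <- function(ann) ann@genes

#' Reference transcripts
#' @param ann a [GenomeAnnotation]
#' @export
refTranscripts <- function(ann) ann@transcripts

#' Spliced transcript sequence in transcription order
#'
#' Concatenates the exon substrings in genomic order and reverse-complements
#' the result for minus-strand transcripts.
#'
#' @param ts a [TranscriptSet]
#' @param id transcript id or index
#' @param genome a named [Biostrings::DNAStringSet] keyed by chromosome
#' @return character DNA string of length `sum(exon lengths)`
#' @export
transcriptSequence <- function(ts, id, genome) {
  i <- if (is.character(id)) match(id, ts@info$transcript_id) else id
  chrom <- ts@info$chrom[i]
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " absent from genome")
  chrlen <- length(genome[[chrom]])
  ex <- ts@exons[[i]]
  if (any(ex[, 1] < 0) || any(ex[, 2] > chrlen))
    stop("transcript ", ts@info$transcript_id[i],
         " has exons outside chromosome bounds")
  parts <- Biostrings::DNAStringSet(genome[[chrom]],
                                    start = ex[, 1] + 1L, end = ex[, 2])
  s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (ts@info$strand[i] == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# Map a transcript coordinate (0-based, transcription order) to the genomic
# coordinate of that boundary. pos in [0, length]; boundary semantics so that
# mapping an interval [s, e) gives its genomic span.
txToGenomic <- function(ts, id, pos) {
  i <- if (is.character(id)) match(id, ts@info$transcript_id) else id
  ex <- ts@exons[[i]]
  lens <- ex[, 2] - ex[, 1]
  if (ts@info$strand[i] == "+") {
    cum <- c(0L, cumsum(lens))
    vapply(pos, function(p) {
      k <- findInterval(p, cum, rightmost.closed = FALSE)
      k <- min(max(k, 1L), nrow(ex))
      ex[k, 1] + (p - cum[k])
    }, numeric(1))
  } else {
    lens_t <- rev(lens)
    cum <- c(0L, cumsum(lens_t))
    vapply(pos, function(p) {
      k <- findInterval(p, cum, rightmost.closed = FALSE)
      k <- min(max(k, 1L), nrow(ex))
      gk <- nrow(ex) - k + 1L  # genomic index of k-th transcription exon
      ex[gk, 2] - (p - cum[k])
    }, numeric(1))
  }
}

# Transcript coordinate of the last junction (transcription order); NA for
# mono-exonic transcripts.
lastJunctionPos <- function(ts, id) {
  i <- if (is.character(id)) match(id, ts@info$transcript_id) else id
  n <- ts@info$n_exons[i]
  if (n < 2) return(NA_integer_)
  ex <- ts@exons[[i]]
  lens <- ex[, 2] - ex[, 1]
  last_len <- if (ts@info$strand[i] == "+") lens[n] else lens[1]
  as.integer(sum(lens) - last_len)
}
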