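#' @import methods
#' @importFrom stats rnbinom runif rnorm sd pnorm setNames complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

#' A set of transcript models
#'
#' Container for one or more transcript models: per-transcript metadata plus
#' exon structure in genomic coordinates. Coordinates are 0-based half-open
#' throughout; exons are stored in ascending genomic order and introns are
#' derived at construction time. Splice junctions can be retrieved in
#' transcription order (donor = boundary adjacent to the upstream exon on the
#' transcript's strand) via [txJunctions()], which makes every downstream
#' splice rule strand-free.
#'
#' @slot info `data.frame` with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `n_exons`, `length`
#'   (spliced length in nt).
#' @slot exons named list of integer matrices (columns `start`, `end`), one
#'   per transcript, rows in ascending genomic order.
#' @slot introns named list of integer matrices (columns `left`, `right`),
#'   the gaps between consecutive exons in genomic order (`n_exons - 1` rows).
#' @slot chainKey character vector of junction-chain keys
#'   (`chrom:strand:l-r;l-r;...`), `NA` for mono-exonic transcripts.
#'
#' @seealso [makeTranscriptSet()], [readGtf()]
#' @export
setClass("TranscriptSet",
  representation(
    info = "data.frame",
    exons = "list",
    introns = "list",
    chainKey = "character"
  )
)

setValidity("TranscriptSet", function(object) {
  info <- object@info
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end",
            "n_exons", "length")
  if (!all(need %in% names(info)))
    return(paste("info must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(info$transcript_id))
    return("duplicated transcript_id")
  if (length(object@exons) != nrow(info) ||
      length(object@introns) != nrow(info) ||
      length(object@chainKey) != nrow(info))
    return("slot lengths disagree with number of transcripts")
  if (!all(info$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  for (i in seq_len(nrow(info))) {
    ex <- object@exons[[i]]
    if (any(ex[, 2] <= ex[, 1]))
      return(sprintf("transcript %s: exon with end <= start",
                     info$transcript_id[i]))
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
      return(sprintf("transcript %s: exons overlap or are unsorted",
                     info$transcript_id[i]))
  }
  TRUE
})

#' Reference genome annotation with splice-site and junction-chain indexes
#'
#' Holds the reference transcript models together with the derived per-gene
#' indexes the classifier needs: the set of annotated donor and acceptor
#' positions per gene, the unique annotated introns per gene, and a global
#' junction-chain index mapping each multi-exonic reference chain to the
#' transcripts carrying it.
#'
#' @slot transcripts a [TranscriptSet] of reference transcripts.
#' @slot genes `data.frame`: `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `lncrna` (logical biotype flag).
#' @slot siteIndex named list, per gene: `list(donors=, acceptors=)` of
#'   genomic positions.
#' @slot chainIndex named list mapping junction-chain key to the reference
#'   transcript ids sharing that chain (multi-exonic transcripts only).
#' @slot intronIndex named list, per gene: integer matrix (columns `left`,
#'   `right`) of distinct annotated introns.
#' @slot geneTx named list, per gene: reference transcript ids.
#'
#' @seealso [buildAnnotation()], [readGtf()]
#' @export
setClass("GenomeAnnotation",
  representation(
    transcripts = "TranscriptSet",
    genes = "data.frame",
    siteIndex = "list",
    chainIndex = "list",
    intronIndex = "list",
    geneTx = "list"
  )
)

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  need <- c("gene_id", "chrom", "strand", "start", "end", "lncrna")
  if (!all(need %in% names(g)))
    return(paste("genes must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene_id)) return("duplicated gene_id")
  if (!all(names(object@siteIndex) %in% g$gene_id))
    return("siteIndex names must be gene ids")
  TRUE
})

#' @describeIn TranscriptSet number of transcripts
#' @param x a `TranscriptSet`
#' @export
setMethod("length", "TranscriptSet", function(x) nrow(x@info))

#' @describeIn TranscriptSet transcript ids
#' @export
setMethod("names", "TranscriptSet", function(x) x@info$transcript_id)

#' @describeIn TranscriptSet subset by index or transcript id
#' @param i integer, logical or character index
#' @param j,drop,... ignored
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@info$transcript_id)
    if (anyNA(idx)) stop("unknown transcript id(s): ",
                         paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  info <- x@info[i, , drop = FALSE]
  rownames(info) <- NULL
  new("TranscriptSet",
      info = info, exons = x@exons[i],
      introns = x@introns[i],
      chainKey = x@chainKey[i])
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts on",
      length(unique(object@info$chrom)), "sequence(s)\n")
  n <- min(5L, length(object))
  if (n > 0) {
    cat("  first ids:", paste(head(object@info$transcript_id, n),
                              collapse = ", "), "\n")
    cat("  exon counts:", paste(range(object@info$n_exons), collapse = "-"),
        "\n")
  }
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", nrow(object@genes), "genes,",
      length(object@transcripts), "reference transcripts,",
      length(object@chainIndex), "distinct junction chains\n")
})
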