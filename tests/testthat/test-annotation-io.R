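# GTF/BED/FASTA/counts I/O and the coordinate-normalized transcript model.

gtf_line <- function(chrom, feat, s, e, strand, attrs) {
  paste(chrom, "src", feat, s, e, ".", strand, ".", attrs, sep = "\t")
}

test_that("GTF coordinates convert to 0-based half-open and strand
           conventions hold", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "exon", 101, 200, "+",
             'gene_id "g1"; transcript_id "t1";'),
    gtf_line("chr1", "exon", 301, 400, "+",
             'gene_id "g1"; transcript_id "t1";'),
    gtf_line("chr1", "exon", 401, 500, "-",
             'gene_id "g2"; transcript_id "t2";'),
    gtf_line("chr1", "exon", 601, 700, "-",
             'gene_id "g2"; transcript_id "t2";')), f)
  ts <- readGtf(f, kind = "query")
  expect_equal(unname(txExons(ts, "t1")[1, ]), c(100L, 200L))
  expect_equal(unname(txExons(ts, "t1")[2, ]), c(300L, 400L))
  # minus strand: genomic intron [500, 600) reads donor 600, acceptor 500
  j <- txJunctions(ts, "t2")
  expect_equal(unname(j[1, "donor"]), 600L)
  expect_equal(unname(j[1, "acceptor"]), 500L)
  expect_equal(txInfo(ts)$n_exons, c(2L, 2L))
})

test_that("GTF round-trip is lossless, including escaped attributes", {
  ts <- makeTranscriptSet(data.frame(
    transcript_id = rep(c("t1", "t2"), each = 2),
    gene_id = rep(c("g1", "g2"), each = 2),
    chrom = "chr3", strand = rep(c("+", "-"), each = 2),
    start = c(0, 500, 1000, 2000), end = c(100, 700, 1500, 2500)))
  f <- withr::local_tempfile(fileext = ".gtf")
  writeGtf(ts, f, annotations = list(
    t1 = c(note = 'he said "hi"', structural_category = "FSM")))
  back <- readGtf(f, kind = "query")
  expect_equal(txInfo(back)[, names(txInfo(ts))], txInfo(ts))
  expect_equal(txExons(back, "t2"), txExons(ts, "t2"))
  at <- attr(back, "attributes")
  expect_equal(unname(at$t1["note"]), 'he said "hi"')
  expect_equal(unname(at$t1["structural_category"]), "FSM")
  # empty set gives a header-only file that reads back empty
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeGtf(makeTranscriptSet(data.frame(transcript_id = character(),
                                        chrom = character(),
                                        strand = character(),
                                        start = integer(),
                                        end = integer())), f2)
  expect_equal(length(readGtf(f2, kind = "query")), 0L)
})

test_that("written GTF agrees with an independent GTF reader", {
  skip_if_not_installed("rtracklayer")
  ts <- makeTranscriptSet(data.frame(
    transcript_id = rep("t1", 3), gene_id = "g1", chrom = "chr1",
    strand = "-", start = c(10, 300, 900), end = c(100, 450, 1000)))
  f <- withr::local_tempfile(fileext = ".gtf")
  writeGtf(ts, f)
  gr <- rtracklayer::import(f)
  ex <- gr[gr$type == "exon"]
  expect_equal(BiocGenerics::start(ex), c(11L, 301L, 901L))
  expect_equal(BiocGenerics::end(ex), c(100L, 450L, 1000L))
  expect_equal(as.character(BiocGenerics::strand(ex)), rep("-", 3))
  expect_equal(ex$transcript_id, rep("t1", 3))
})

test_that("GTF parse and validation errors are informative", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "exon", 1, 100, "+",
             'gene_id "g"; transcript_id "t";'),
    "chr1\tonly\tthree"), f)
  expect_error(readGtf(f), "line 2")
  writeLines(gtf_line("chr1", "exon", 500, 100, "+",
                      'gene_id "g"; transcript_id "t";'), f)
  expect_error(readGtf(f), "end < start")
  writeLines(c(
    gtf_line("chr1", "exon", 1, 100, "+",
             'gene_id "g"; transcript_id "t";'),
    gtf_line("chr2", "exon", 201, 300, "+",
             'gene_id "g"; transcript_id "t";')), f)
  expect_error(readGtf(f), "multiple chromosomes")
})

test_that("reference GTF builds gene, site and chain indexes, with gene
           extents inferred when gene lines are absent", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "exon", 1, 100, "+",
             'gene_id "g1"; transcript_id "r1";'),
    gtf_line("chr1", "exon", 201, 300, "+",
             'gene_id "g1"; transcript_id "r1";'),
    gtf_line("chr1", "exon", 1, 100, "+",
             'gene_id "g1"; transcript_id "r2";'),
    gtf_line("chr1", "exon", 401, 500, "+",
             'gene_id "g1"; transcript_id "r2";')), f)
  ann <- readGtf(f, kind = "reference")
  g <- refGenes(ann)
  expect_equal(g$gene_id, "g1")
  expect_equal(g$start, 0L)
  expect_equal(g$end, 500L)
  expect_equal(length(refTranscripts(ann)), 2L)
})

test_that("counts, BED and FASTA readers validate their inputs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tA\tB", "t1\t3\t5", "t2\t0\t1"), f)
  m <- readCounts(f)
  expect_equal(m["t1", "A"], 3)
  writeLines(c("transcript_id\tA", "t1\t-1"), f)
  expect_error(readCounts(f), "negative")
  writeLines(c("transcript_id\tA", "t1\t1", "t1\t2"), f)
  expect_error(readCounts(f), "duplicate transcript")

  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t90\t110", b)
  peaks <- readBed(b)
  expect_equal(peaks$start, 90L)
  expect_equal(peaks$end, 110L)
  writeLines("chr1\t90", b)
  expect_error(readBed(b), "fewer than 3")

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrZ desc", paste(rep("ACGTA", 10), collapse = "")), fa)
  g <- readFasta(fa)
  expect_equal(names(g), "chrZ")
  expect_error(genomeSubseq(g, "chrZ", 45, 55), "outside bounds")
  expect_error(genomeSubseq(g, "nope", 0, 5), "absent")
})

test_that("transcript sequences are spliced in transcription order", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATTGGGCCC", chr2 = "ATGC"))
  plus <- makeTranscriptSet(data.frame(
    transcript_id = "p", chrom = "chr1", strand = "+",
    start = c(0, 6), end = c(3, 9)))
  expect_equal(transcriptSequence(plus, "p", g), "ATTCCC")
  minus <- makeTranscriptSet(data.frame(
    transcript_id = "m", chrom = "chr2", strand = "-",
    start = 0, end = 4))
  expect_equal(transcriptSequence(minus, "m", g), "GCAT")
  # plus-strand sequence is the reverse complement of the same exons on minus
  minus2 <- makeTranscriptSet(data.frame(
    transcript_id = "m2", chrom = "chr1", strand = "-",
    start = c(0, 6), end = c(3, 9)))
  expect_equal(
    transcriptSequence(minus2, "m2", g),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(transcriptSequence(plus, "p", g)))))
})

test_that("sequence length equals the exon-length sum on random
           transcripts", {
  set.seed(42)
  g <- Biostrings::DNAStringSet(c(chrR = paste(
    sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")))
  for (k in 1:200) {
    n <- sample(1:6, 1)
    starts <- sort(sample(seq(0, 49000, by = 120), n))
    lens <- sample(20:100, n, TRUE)
    ts <- makeTranscriptSet(data.frame(
      transcript_id = "t", chrom = "chrR",
      strand = sample(c("+", "-"), 1), start = starts,
      end = starts + lens))
    expect_equal(nchar(transcriptSequence(ts, 1, g)), sum(lens))
  }
})

test_that("junction count and coordinates follow from the exon structure", {
  set.seed(9)
  for (k in 1:50) {
    n <- sample(2:7, 1)
    starts <- cumsum(sample(100:300, n, TRUE)) + 1000L
    lens <- sample(50:90, n, TRUE)
    strand <- sample(c("+", "-"), 1)
    ts <- makeTranscriptSet(data.frame(
      transcript_id = "t", chrom = "c", strand = strand,
      start = starts, end = starts + lens))
    j <- txJunctions(ts, 1)
    expect_equal(nrow(j), n - 1L)
    ex <- txExons(ts, 1)
    gaps_left <- ex[-n, 2]; gaps_right <- ex[-1, 1]
    if (strand == "+") {
      expect_equal(unname(j[, "donor"]), unname(gaps_left))
      expect_equal(unname(j[, "acceptor"]), unname(gaps_right))
    } else {
      expect_equal(unname(j[, "donor"]), unname(rev(gaps_right)))
      expect_equal(unname(j[, "acceptor"]), unname(rev(gaps_left)))
    }
  }
})
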