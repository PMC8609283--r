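# Structural classification against a hand-built reference and against the
# brute-force oracle on generator output.

toy_reference <- function() {
  # gene gA (+): r1 = exons [0,100) [200,300) [400,500) [600,700)
  #              r2 = r1 without exon 2
  # gene gB (+): [2000,2100) [2200,2300), adjacent and disjoint from gA
  # gene gC (-): [5000,5100) [5200,5300)
  df <- rbind(
    data.frame(transcript_id = "r1", gene_id = "gA", chrom = "chr1",
               strand = "+", start = c(0, 200, 400, 600),
               end = c(100, 300, 500, 700)),
    data.frame(transcript_id = "r2", gene_id = "gA", chrom = "chr1",
               strand = "+", start = c(0, 400, 600),
               end = c(100, 500, 700)),
    data.frame(transcript_id = "rB", gene_id = "gB", chrom = "chr1",
               strand = "+", start = c(2000, 2200), end = c(2100, 2300)),
    data.frame(transcript_id = "rC", gene_id = "gC", chrom = "chr1",
               strand = "-", start = c(5000, 5200), end = c(5100, 5300)))
  buildAnnotation(makeTranscriptSet(df))
}

q1 <- function(id, starts, ends, strand = "+") {
  makeTranscriptSet(data.frame(transcript_id = id, chrom = "chr1",
                               strand = strand, start = starts,
                               end = ends))
}

test_that("the forced category examples classify as defined", {
  ann <- toy_reference()
  # identical chain -> FSM with the matching reference
  r <- classifyTranscript(q1("t", c(0, 200, 400, 600),
                             c(100, 300, 500, 700)), 1, ann)
  expect_equal(r$category, "FSM")
  expect_equal(r$associated_transcript, "r1")
  expect_equal(r$associated_genes, "gA")
  # chain dropping the 5'-most junction -> ISM (5' fragment)
  r <- classifyTranscript(q1("t", c(220, 400, 600), c(300, 500, 700)),
                          1, ann)
  expect_equal(r$category, "ISM")
  expect_equal(r$associated_transcript, "r1")
  expect_equal(r$ism_subtype, "5prime_fragment")
  # skipping an annotated exon with annotated sites -> NIC... unless the
  # skip reproduces another reference chain (here r2), which is FSM
  r <- classifyTranscript(q1("t", c(0, 400, 600), c(100, 500, 700)), 1, ann)
  expect_equal(r$category, "FSM")
  expect_equal(r$associated_transcript, "r2")
  # novel recombination of annotated sites -> NIC
  r <- classifyTranscript(q1("t", c(0, 200, 600), c(100, 300, 700)), 1, ann)
  expect_equal(r$category, "NIC")
  expect_equal(r$associated_transcript, "novel")
  # one shifted donor -> NNC
  r <- classifyTranscript(q1("t", c(0, 200, 400, 600),
                             c(100, 310, 500, 700)), 1, ann)
  expect_equal(r$category, "NNC")
  # spanning two disjoint genes -> fusion with both genes
  r <- classifyTranscript(q1("t", c(0, 200, 400, 600, 2000, 2200),
                             c(100, 300, 500, 700, 2100, 2300)), 1, ann)
  expect_equal(r$category, "fusion")
  expect_equal(r$associated_genes, "gA;gB")
  # mono-exonic across an exon/intron boundary -> genic_genomic
  r <- classifyTranscript(q1("t", 250, 350), 1, ann)
  expect_equal(r$category, "genic_genomic")
  # mono-exonic inside an annotated intron -> genic_intron
  r <- classifyTranscript(q1("t", 320, 380), 1, ann)
  expect_equal(r$category, "genic_intron")
  # opposite-strand overlap only -> antisense
  r <- classifyTranscript(q1("t", c(5000, 5200), c(5100, 5300), "+"), 1, ann)
  expect_equal(r$category, "antisense")
  expect_equal(r$associated_genes, "gC")
  # nothing anywhere near -> intergenic
  r <- classifyTranscript(q1("t", c(40000, 40500), c(40100, 40600)), 1, ann)
  expect_equal(r$category, "intergenic")
  expect_equal(r$associated_genes, "")
})

test_that("categories are exhaustive and exclusive, and classifyAll equals
           independent per-transcript calls", {
  sim <- simulateReference(smallSimConfig(21))
  qs <- simulateQueries(smallSimConfig(21), sim)
  kept <- removeFragments(qs$queries)$kept
  cl <- classifyAll(kept, sim$annotation)
  expect_equal(nrow(cl), length(kept))
  expect_true(all(cl$category %in%
                    c("FSM", "ISM", "NIC", "NNC", "fusion", "antisense",
                      "intergenic", "genic_genomic", "genic_intron")))
  expect_equal(sum(table(cl$category)), length(kept))
  # compositional: per-transcript classification agrees
  idx <- seq(1, length(kept), by = 7)
  for (i in idx) {
    one <- classifyTranscript(kept, i, sim$annotation)
    expect_equal(one$category, cl$category[i])
    expect_equal(one$associated_transcript, cl$associated_transcript[i])
  }
  expect_equal(nrow(classifyAll(kept[integer(0)], sim$annotation)), 0L)
})

test_that("classifier agrees with the brute-force oracle on generator
           transcripts", {
  cfg <- smallSimConfig(31)
  sim <- simulateReference(cfg)
  qs <- simulateQueries(cfg, sim)
  kept <- removeFragments(qs$queries)$kept
  cl <- classifyAll(kept, sim$annotation)
  or <- oracleClassify(kept, sim$annotation)
  expect_equal(cl$category, or$category)
  expect_equal(cl$associated_genes, or$associated_genes)
  expect_equal(cl$associated_transcript, or$associated_transcript)
})

test_that("FSM calls are invariant under the fragment filter and IR only
           occurs in categories that can contain a reference intron", {
  cfg <- smallSimConfig(5)
  sim <- simulateReference(cfg)
  qs <- simulateQueries(cfg, sim)
  cl_all <- classifyAll(qs$queries, sim$annotation)
  kept <- removeFragments(qs$queries)$kept
  cl_kept <- classifyAll(kept, sim$annotation)
  fsm_before <- cl_all$transcript_id[cl_all$category == "FSM"]
  fsm_after <- cl_kept$transcript_id[cl_kept$category == "FSM"]
  expect_setequal(intersect(fsm_before, names(kept)), fsm_after)
  expect_true(all(fsm_before %in% names(kept)))
  expect_true(all(cl_kept$category[cl_kept$ir_flag] %in%
                    c("NIC", "NNC", "fusion", "genic_genomic")))
})

test_that("planted truth labels are recovered on the small generator
           config", {
  cfg <- smallSimConfig(13)
  sim <- simulateReference(cfg)
  qs <- simulateQueries(cfg, sim)
  fr <- removeFragments(qs$queries)
  expect_setequal(fr$removed_fragment_ids,
                  qs$truth$transcript_id[qs$truth$fragment])
  cl <- classifyAll(fr$kept, sim$annotation, genome = sim$genome)
  tr <- qs$truth[!qs$truth$fragment, ]
  m <- match(tr$transcript_id, cl$transcript_id)
  expect_equal(cl$category[m], tr$category)
  expect_equal(cl$associated_genes[m], tr$genes)
  expect_equal(cl$associated_transcript[m], tr$associated_transcript)
  expect_equal(cl$ir_flag[m], tr$ir)
  expect_equal(cl$intrapriming_flag[m], tr$intrapriming)
})
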