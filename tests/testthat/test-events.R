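# Local AS-event enumeration: forced examples, strand flips, oracle
# equivalence and the catalog invariants.

mk_gene <- function(exlist, strand, ids = sprintf("t%d", seq_along(exlist)),
                    gene = "g1") {
  df <- do.call(rbind, lapply(seq_along(exlist), function(t)
    data.frame(transcript_id = ids[t], gene_id = gene, chrom = "chr1",
               strand = strand, start = exlist[[t]][, 1],
               end = exlist[[t]][, 2], stringsAsFactors = FALSE)))
  makeTranscriptSet(df)
}

grp_of <- function(ts, gene = "g1") setNames(rep(gene, length(ts)),
                                             names(ts))

test_that("a skipped exon yields one SE with the defining junction key", {
  ts <- mk_gene(list(cbind(c(0, 200, 400), c(100, 300, 500)),
                     cbind(c(0, 400), c(100, 500))), "+")
  ev <- enumerateEvents(ts, grp_of(ts))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "SE")
  expect_equal(ev$key, "100,200,300,400")
  expect_equal(ev$inclusion_transcripts, "t1")
  expect_equal(ev$exclusion_transcripts, "t2")
})

test_that("the same exon structure is A5 on plus and A3 on minus strand", {
  exl <- list(cbind(c(0, 400), c(100, 500)),
              cbind(c(0, 400), c(150, 500)))
  evp <- enumerateEvents(mk_gene(exl, "+"), grp_of(mk_gene(exl, "+")))
  expect_equal(evp$event_type, "A5")
  expect_equal(evp$key, "100,150,400")
  evm <- enumerateEvents(mk_gene(exl, "-"), grp_of(mk_gene(exl, "-")))
  expect_equal(evm$event_type, "A3")
  expect_equal(evm$key, "400,100,150")
})

test_that("alternative first exons suppress the co-located A5 and carry the
           two exon spans in the key", {
  exl <- list(cbind(c(0, 500), c(100, 600)),
              cbind(c(200, 500), c(300, 600)))
  ts <- mk_gene(exl, "+")
  ev <- enumerateEvents(ts, grp_of(ts))
  expect_equal(ev$event_type, "AF")
  expect_equal(ev$key, "0,100,200,300,500")
  tsm <- mk_gene(exl, "-")
  evm <- enumerateEvents(tsm, grp_of(tsm))
  expect_equal(evm$event_type, "AL")
})

test_that("mutually exclusive exons require shared flanks and disjoint
           middles", {
  exl <- list(cbind(c(0, 200, 600), c(100, 300, 700)),
              cbind(c(0, 400, 600), c(100, 500, 700)))
  ts <- mk_gene(exl, "+")
  ev <- enumerateEvents(ts, grp_of(ts))
  expect_equal(ev$event_type, "MX")
  expect_equal(ev$key, "100,200,300,400,500,600")
  # overlapping middles are not MX
  exl2 <- list(cbind(c(0, 200, 600), c(100, 300, 700)),
               cbind(c(0, 250, 600), c(100, 500, 700)))
  ts2 <- mk_gene(exl2, "+")
  expect_false(any(enumerateEvents(ts2, grp_of(ts2))$event_type == "MX"))
})

test_that("enumerateEvents equals the exhaustive pairwise oracle on random
           genes", {
  set.seed(101)
  for (k in 1:80) {
    g <- randomEventGene()
    ts <- eventGeneToSet(g)
    ev <- enumerateEvents(ts, setNames(rep("gX", length(ts)), names(ts)))
    or <- oracleGeneEvents(g$exons, g$strand, g$ids)
    got <- ev[order(ev$event_type, ev$key),
              c("event_type", "key", "inclusion_transcripts",
                "exclusion_transcripts")]
    want <- or[order(or$event_type, or$key), ]
    rownames(got) <- NULL; rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("the catalog is invariant under transcript order, deduplicates
           support, and never gains keys when transcripts are removed", {
  set.seed(55)
  for (k in 1:25) {
    g <- randomEventGene(n_tx = 4)
    ts <- eventGeneToSet(g)
    ev <- enumerateEvents(ts, grp_of(ts, "gX"))
    perm <- sample(length(ts))
    tsp <- ts[perm]
    evp <- enumerateEvents(tsp, grp_of(tsp, "gX"))
    expect_equal(ev[order(ev$key, ev$event_type), ],
                 evp[order(evp$key, evp$event_type), ],
                 ignore_attr = TRUE)
    # duplicate of t1 changes support lists only
    dup <- g
    dup$exons <- c(dup$exons, dup$exons[1])
    dup$ids <- c(dup$ids, "t99")
    tsd <- eventGeneToSet(dup)
    evd <- enumerateEvents(tsd, grp_of(tsd, "gX"))
    expect_setequal(paste(ev$event_type, ev$key),
                    paste(evd$event_type, evd$key))
    # removing a transcript is monotone in the key set
    tsr <- ts[-1]
    evr <- enumerateEvents(tsr, grp_of(tsr, "gX"))
    expect_true(all(paste(evr$event_type, evr$key) %in%
                      paste(ev$event_type, ev$key)))
  }
})

test_that("each planted single-event gene yields exactly its event", {
  cfg <- smallSimConfig(3)
  sim <- simulateReference(cfg)
  qs <- simulateQueries(cfg, sim)
  tr <- qs$truth
  ev_tx <- tr$transcript_id[grepl("^event_", tr$role)]
  ts <- qs$queries[ev_tx]
  gene_of <- setNames(tr$genes[match(ev_tx, tr$transcript_id)], ev_tx)
  ev <- enumerateEvents(ts, gene_of)
  et <- qs$event_truth
  expect_equal(nrow(ev), nrow(et))
  expect_setequal(paste(ev$gene_id, ev$event_type, ev$key),
                  paste(et$gene_id, et$event_type, et$key))
})

test_that("IR aggregation partitions genes by their IR transcripts", {
  cl <- data.frame(
    transcript_id = sprintf("t%d", 1:6),
    associated_genes = c("g1", "g1", "g1", "g2", "g2", ""),
    ir_flag = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  r <- irAggregate(cl)
  expect_setequal(r$ir_transcripts, c("t1", "t2", "t3", "t4", "t6"))
  expect_setequal(r$ir_genes, c("g1", "g2"))
  expect_equal(r$only_ir_genes, "g1")
})

test_that("per-gene summaries count events and break predominance ties in
           the fixed order", {
  ev <- data.frame(
    gene_id = c("g1", "g1", "g1", "g1", "g2", "g2"),
    event_type = c("AF", "AF", "AF", "SE", "SE", "AF"),
    key = sprintf("k%d", 1:6))
  s <- perGeneEventSummary(ev)
  expect_equal(s$predominant[s$gene_id == "g1"], "AF")
  expect_equal(s$AF[s$gene_id == "g1"], 3)
  # 1 AF vs 1 SE ties to AF
  expect_equal(s$predominant[s$gene_id == "g2"], "AF")
  expect_equal(sum(s$AF) + sum(s$SE), nrow(ev))
})

test_that("the events TSV is deterministic and re-parses to the catalog", {
  set.seed(8)
  g <- randomEventGene(n_tx = 5)
  ts <- eventGeneToSet(g)
  ev <- enumerateEvents(ts, setNames(rep("gX", length(ts)), names(ts)))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeEvents(ev, f1)
  writeEvents(ev, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- readEvents(f1)
  expect_equal(nrow(back), nrow(ev))
  expect_setequal(paste(back$event_type, back$key),
                  paste(ev$event_type, ev$key))
})
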