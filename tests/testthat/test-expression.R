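# TPM normalization, gene aggregation, diversity, rarefaction, DTE/DTU.

mat <- function(x, samples = LETTERS[seq_len(ncol(x))]) {
  colnames(x) <- samples
  rownames(x) <- sprintf("t%d", seq_len(nrow(x)))
  x
}

test_that("TPM columns sum to one million and are scale invariant", {
  m <- mat(matrix(c(1, 1, 2), 3, 1))
  se <- tpmNormalize(m)
  expect_equal(unname(tpmAssay(se)[, 1]), c(250000, 250000, 500000))
  set.seed(2)
  m2 <- mat(matrix(rpois(60, 40) + 1, 20, 3))
  se2 <- tpmNormalize(m2)
  expect_equal(unname(colSums(tpmAssay(se2))), rep(1e6, 3))
  expect_equal(tpmAssay(tpmNormalize(m2 * 7)), tpmAssay(se2))
  m2[, 2] <- 0
  expect_error(tpmNormalize(m2), "B")
})

test_that("gene aggregation sums member counts with the mono-exonic and
           fusion exclusions", {
  counts <- mat(matrix(c(5, 7, 7, 3, 2, 2, 9, 1), 4, 2))
  cl <- data.frame(
    transcript_id = rownames(counts),
    associated_genes = c("g1", "g1", "g1", "g2;g3"),
    category = c("FSM", "NIC", "FSM", "fusion"),
    n_exons = c(3, 2, 1, 4))
  se <- tpmNormalize(counts)
  g_on <- geneAggregate(se, cl, drop_monoexonic = TRUE)
  expect_equal(unname(countsAssay(g_on)["g1", ]), c(5 + 7, 2 + 2))
  g_off <- geneAggregate(se, cl, drop_monoexonic = FALSE)
  expect_equal(unname(countsAssay(g_off)["g1", ]), c(19, 13))
  expect_false("g2;g3" %in% rownames(countsAssay(g_on)))
  bad <- counts
  rownames(bad)[1] <- "zz"
  expect_error(geneAggregate(tpmNormalize(bad), cl), "absent")
})

test_that("diversity correlations behave on degenerate and random input and
           match the textbook formula", {
  mk_cl <- function(n_per_gene, lens, exons) {
    genes <- sprintf("g%d", seq_along(n_per_gene))
    tx <- unlist(lapply(seq_along(genes), function(i)
      sprintf("%s.t%d", genes[i], seq_len(n_per_gene[i]))))
    data.frame(transcript_id = tx,
               associated_genes = rep(genes, n_per_gene),
               category = "FSM", stringsAsFactors = FALSE)
  }
  set.seed(4)
  n_per_gene <- sample(1:12, 40, TRUE)
  cl <- mk_cl(n_per_gene)
  rows <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    g <- as.integer(sub("^g(\\d+)\\..*", "\\1", cl$transcript_id[i]))
    span <- 1000 + 500 * g
    data.frame(transcript_id = cl$transcript_id[i], chrom = "c",
               strand = "+", start = c(0, span - 100),
               end = c(100, span))
  }))
  ts <- makeTranscriptSet(rows)
  d <- diversityStats(cl, ts)
  expect_equal(nrow(d$per_gene), 40)
  expect_equal(d$genes_gt1, sum(n_per_gene > 1))
  expect_equal(d$genes_gt10, sum(n_per_gene > 10))
  want <- stats::cor(d$per_gene$n_isoforms, log10(d$per_gene$gene_length))
  expect_equal(d$cor_length, want, tolerance = 1e-12)
  # identical vectors correlate perfectly; constants are undefined
  expect_equal(stats::cor(1:5, 1:5), 1)
  cl1 <- mk_cl(rep(2, 2))
  rows1 <- do.call(rbind, lapply(cl1$transcript_id, function(id)
    data.frame(transcript_id = id, chrom = "c", strand = "+",
               start = c(0, 900), end = c(100, 1000))))
  d1 <- diversityStats(cl1, makeTranscriptSet(rows1))
  expect_true(is.na(d1$cor_length))
})

test_that("rarefaction is exact at the depth extremes and matches the
           hypergeometric expectation in between", {
  set.seed(12)
  n_i <- rpois(60, 8) + 1
  reads <- rep(sprintf("t%d", seq_along(n_i)), n_i)
  N <- length(reads)
  r <- rarefactionCurve(reads, depths = c(0, round(N / 3), N), reps = 60,
                        seed = 99)
  expect_equal(r$mean_transcripts[1], 0)
  expect_equal(r$mean_transcripts[3], 60)
  expect_true(all(diff(r$mean_transcripts) >= 0))
  d <- round(N / 3)
  expected <- rarefactionExpected(n_i, d)
  se_mc <- r$sd_transcripts[2] / sqrt(60)
  expect_lt(abs(r$mean_transcripts[2] - expected), 3 * se_mc + 1e-9)
  expect_error(rarefactionCurve(reads, depths = N + 1), "exceeds")
})

test_that("the exact Wilcoxon branch reproduces enumeration and the tied
           branch uses the corrected normal approximation", {
  counts <- rbind(t1 = c(1, 2, 3, 4, 10, 11, 12),
                  t2 = c(5, 5, 5, 5, 5, 5, 5))
  colnames(counts) <- sprintf("s%d", 1:7)
  se <- tpmNormalize(counts + 0)
  # complete separation at n = 4 vs 3: p = 2/35 by labeling enumeration
  tpm <- tpmAssay(se)
  d <- dteWilcoxon(se, sprintf("s%d", 1:4), sprintf("s%d", 5:7))
  expect_equal(d$p_value[1], 2 / 35, tolerance = 1e-12)
  expect_equal(d$p_value[1],
               oracleWilcoxonExact(tpm[1, 1:4], tpm[1, 5:7]),
               tolerance = 1e-12)
  expect_true(d$exact[1])
  expect_equal(d$direction[1], -1L)
  # identical multisets in both groups: symmetric null
  m2 <- rbind(t1 = c(1, 2, 3, 1, 2, 3), anchor = 1000)
  colnames(m2) <- sprintf("s%d", 1:6)
  d2 <- dteWilcoxon(tpmNormalize(m2), sprintf("s%d", 1:3),
                    sprintf("s%d", 4:6))
  expect_equal(d2$p_value[1], 1)
  # constant values across every sample also resolve to the null
  expect_equal(d2$p_value[2], 1)
  expect_error(dteWilcoxon(se, "s1", sprintf("s%d", 5:7)), "two samples")
})

test_that("exact p-values match the enumeration oracle on random tie-free
           instances", {
  set.seed(606)
  for (k in 1:60) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- round(runif(na, 0, 100), 6); y <- round(runif(nb, 0, 100), 6)
    if (anyDuplicated(c(x, y))) next
    counts <- matrix(c(x, y), 1,
                     dimnames = list("t1", sprintf("s%d", seq_len(na + nb))))
    counts <- rbind(counts, anchor = 1000)  # keep column totals positive
    se <- tpmNormalize(counts)
    d <- dteWilcoxon(se, sprintf("s%d", seq_len(na)),
                     sprintf("s%d", na + seq_len(nb)))
    tpm <- tpmAssay(se)
    want <- oracleWilcoxonExact(tpm[1, seq_len(na)],
                                tpm[1, na + seq_len(nb)])
    expect_equal(d$p_value[1], want, tolerance = 1e-12)
  }
})

test_that("the fetal/adult DTU rule needs opposite-direction significance
           with the TPM gate on both transcripts", {
  base <- data.frame(
    transcript_id = c("a", "b", "c", "d"),
    delta = c(50, -60, 40, -10),
    p_value = c(0.01, 0.02, 0.2, 0.01))
  tx2gene <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  r <- dtuFetalAdult(base, tx2gene)
  expect_equal(r$gene_id, "g1")
  expect_equal(r$up_transcripts, "a")
  expect_equal(r$down_transcripts, "b")
  # one significant transcript only -> no call
  one <- base; one$p_value[2] <- 0.5
  expect_equal(nrow(dtuFetalAdult(one, tx2gene)), 0L)
  # delta of 10 fails the strict > 20 gate
  small <- base; small$delta[2] <- -10
  expect_equal(nrow(dtuFetalAdult(small, tx2gene)), 0L)
})

test_that("the region-pair rule gates on pseudocount fold change and
           absolute difference", {
  counts <- rbind(t1 = c(100, 20), t2 = c(30, 10), t3 = c(28, 1),
                  pad = c(1e6 - 158, 1e6 - 31))
  colnames(counts) <- c("r1", "r2")
  se <- tpmNormalize(counts)
  r <- dtuRegionPair(se, "r1", "r2", tx2gene = c(t1 = "g", t2 = "g",
                                                 t3 = "g", pad = "p"))
  tx <- r$transcripts
  expect_true(tx$flagged[tx$transcript_id == "t1"])   # FC 101/21, delta 80
  expect_false(tx$flagged[tx$transcript_id == "t2"])  # FC 31/11 < 4
  expect_true(tx$flagged[tx$transcript_id == "t3"])   # FC 29/2, delta 27
  expect_equal(tx$fold_change[tx$transcript_id == "t1"], 101 / 21)
  # opposite directions needed for a gene call
  expect_equal(nrow(r$genes), 0L)
  counts2 <- rbind(up = c(100, 20), dn = c(20, 100), pad = c(2000, 2000))
  colnames(counts2) <- c("r1", "r2")
  r2 <- dtuRegionPair(tpmNormalize(counts2), "r1", "r2",
                      tx2gene = c(up = "g", dn = "g", pad = "p"))
  expect_equal(r2$genes$gene_id, "g")
})

test_that("group-specific transcripts follow the detection and TPM rules", {
  counts <- rbind(f_only = c(3, 2, 0, 0, 0),
                  both = c(3, 2, 1, 1, 1),
                  a_only = c(0, 0, 5, 4, 6))
  colnames(counts) <- c("f1", "f2", "a1", "a2", "a3")
  groups <- c(f1 = "fetal", f2 = "fetal", a1 = "adult", a2 = "adult",
              a3 = "adult")
  se <- tpmNormalize(counts)
  r <- groupSpecificTranscripts(se, groups, mode = "detection")
  expect_equal(r$fetal, "f_only")
  expect_equal(r$adult, "a_only")
  r2 <- groupSpecificTranscripts(se, groups, mode = "tpm_threshold",
                                 tpm_min = 20)
  direct <- rowMeans(tpmAssay(se)[, c("f1", "f2")])
  expect_true(all(direct[r2$fetal] > 20))
})

test_that("cross-dataset comparison reproduces the identity, relative and
           absolute reference cases", {
  a <- c(g1 = 3, g2 = 12, g3 = 5)
  r <- crossDatasetCompare(a, a)
  expect_equal(r$correlation, 1)
  b <- c(g1 = 3, g2 = 1, g3 = 86)
  r2 <- crossDatasetCompare(a, b)
  tab <- r2$table
  expect_equal(tab$rel_diff[tab$gene_a == "g2"], 12)
  expect_equal(tab$abs_diff[tab$gene_a == "g3"], 81)
  expect_equal(r2$top_absolute$gene_a[1], "g3")
  expect_equal(r2$top_relative$gene_a[1], "g3")  # 86/5 = 17.2 > 12
  hom <- data.frame(a = c("g1", "g1", "g2", "g3"),
                    b = c("g1", "g2", "g2", "g3"))
  expect_message(r3 <- crossDatasetCompare(a, b, hom), "non-unique")
  expect_equal(r3$table$gene_a, "g3")
  expect_error(crossDatasetCompare(a, c(zz = 1)), "no shared genes")
})
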