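# Measurement harnesses shared by the acceptance test and the acceptance
# script. Conditions are the planted-switch design: two transcripts per
# gene with swapped group means of 60 and 5 TPM, negative-binomial
# dispersion 0.3, and a 4 vs 3 group design, at the package's default
# library depth.

# one replicate of the planted-switch experiment; returns per-gene calls
dtuSwitchReplicate <- function(seed, n_switch = 50L, n_null = 50L,
                               n_background = 100L, depth = 2e5,
                               dispersion = 0.3,
                               group_design = c(fetal = 4L, adult = 3L),
                               switch_tpm = c(60, 5)) {
  set.seed(seed)
  ids <- c(sprintf("sw%03d_t%d", rep(seq_len(n_switch), each = 2), 1:2),
           sprintf("nl%03d_t%d", rep(seq_len(n_null), each = 2), 1:2),
           sprintf("bg%03d", seq_len(n_background)))
  gene <- c(sprintf("sw%03d", rep(seq_len(n_switch), each = 2)),
            sprintf("nl%03d", rep(seq_len(n_null), each = 2)),
            sprintf("bgG%03d", seq_len(n_background)))
  tgt <- matrix(NA_real_, length(ids), 2,
                dimnames = list(ids, names(group_design)))
  for (g in seq_len(n_switch)) {
    tgt[2 * g - 1, ] <- switch_tpm
    tgt[2 * g, ] <- rev(switch_tpm)
  }
  null_tpm <- exp(stats::rnorm(2 * n_null, log(40), 0.8))
  tgt[2 * n_switch + seq_len(2 * n_null), 1] <- null_tpm
  tgt[2 * n_switch + seq_len(2 * n_null), 2] <- null_tpm
  bg <- exp(stats::rnorm(n_background, log(2000), 1))
  tgt[2 * (n_switch + n_null) + seq_len(n_background), ] <- cbind(bg, bg)
  sim <- simulateCountsMatrix(tgt, group_design, depth = depth,
                              dispersion = dispersion, seed = seed + 1L)
  se <- tpmNormalize(sim$counts, groups = sim$groups)
  sa <- names(sim$groups)[sim$groups == names(group_design)[1]]
  sb <- names(sim$groups)[sim$groups == names(group_design)[2]]
  dte <- dteWilcoxon(se, sa, sb)
  calls <- dtuFetalAdult(dte, setNames(gene, ids))
  list(called = calls$gene_id,
       switch_genes = sprintf("sw%03d", seq_len(n_switch)),
       null_genes = sprintf("nl%03d", seq_len(n_null)))
}

# pooled precision/recall over seeds plus the per-gene null call rate
dtuSwitchPerformance <- function(n_seeds = 20L, seed0 = 1000L, ...) {
  tp <- fp <- n_sw <- n_nl <- null_calls <- 0L
  for (s in seq_len(n_seeds)) {
    r <- dtuSwitchReplicate(seed0 + s, ...)
    tp <- tp + sum(r$called %in% r$switch_genes)
    fp <- fp + sum(!r$called %in% r$switch_genes)
    null_calls <- null_calls + sum(r$called %in% r$null_genes)
    n_sw <- n_sw + length(r$switch_genes)
    n_nl <- n_nl + length(r$null_genes)
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = tp / n_sw,
       null_call_rate = null_calls / n_nl,
       n_switch = n_sw, n_null = n_nl, n_called = tp + fp)
}
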