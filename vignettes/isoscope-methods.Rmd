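---
title: "Methods and design of the isoscope pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the isoscope pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions
behind `isoscope`: what each stage assumes, which parameters matter and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and where the design was genuinely open.

## Coordinates and the junction-chain model

All internal coordinates are 0-based half-open; GTF input/output converts
at the boundary (BED then needs no conversion and interval arithmetic is
unambiguous). A transcript model is its chromosome, strand and ordered
exons; its introns follow as the gaps between consecutive exons. Splice
junctions are stored as genomic coordinates but labelled and ordered in
*transcription* order — the donor is the intron boundary adjacent to the
upstream exon on the transcript's strand — so every splicing rule in the
package is written once, strand-free. On the minus strand the
transcription-order junction list is the reverse of the genomic-order
intron list with donor and acceptor swapped.

Junction chains are matched **exactly**. No wobble or tolerance enters any
matching step except the fragment filter's 3′ tolerance (below). This is
deliberate: the classification taxonomy is defined on identical splice
junctions, and introducing fuzziness would blur the FSM/ISM/NIC boundary
in ways that are impossible to validate against planted truth. The
practical consequence is that upstream processing is expected to have
already collapsed minor junction wobble.

## Structural classification

Categories are assigned with the precedence FSM > ISM > fusion > NIC >
NNC > genic genomic > genic intron > antisense > intergenic, which makes
them mutually exclusive and exhaustive; a partition check (category counts
summing to the input size) is asserted in the tests.

Decisions taken where the taxonomy leaves room:

* **ISM scope.** ISM accepts any contiguous sub-chain of a reference
  chain, not only 5′-truncations. The canonical description emphasises
  "fewer 5′ exons"; internal and 3′ fragments are structurally the same
  phenomenon, so they are accepted and the anchor is recorded in an
  `ism_subtype` column (`5prime_fragment` when the sub-chain keeps the
  reference's 3′ junctions, `3prime_fragment`, `internal_fragment`), which
  lets a user restrict to strict 5′-truncations after the fact.
* **Match resolution.** When several reference transcripts match (FSM or
  ISM), the one minimizing |ΔTSS| + |ΔTTS| wins; remaining ties resolve to
  the lexicographically smallest transcript id. Determinism here is what
  makes oracle equivalence testable at 100%.
* **NIC site pool.** The donor/acceptor pool is the union over all
  same-strand exon-overlapping ("associated") genes, so NIC is monotone in
  annotation richness: adding reference transcripts can only move
  transcripts from NNC toward NIC, never the reverse.
* **Fusion.** Requires exonic overlap with two or more genes whose
  annotated extents are mutually non-overlapping — read-through between
  adjacent loci. Nested or overlapping gene pairs (common for antisense
  lncRNA annotations) do not trigger fusion; such transcripts fall through
  to the site-based categories.
* **Mono-exonic transcripts** skip the chain-based rules: they are FSM
  only when contained within a mono-exonic reference transcript of an
  overlapping gene, with zero containment tolerance (no wobble is stated
  anywhere, so none is invented), and otherwise fall through to the
  genic/antisense/intergenic rules.
* **IR flag.** A transcript retains an intron when one of its exons
  strictly contains both boundaries of an annotated intron of an
  associated gene. IR is assessed against the reference, not pairwise
  among query transcripts, and coexists with any category that can span a
  reference intron (NIC, NNC, fusion, genic genomic) — an exactly matching
  chain cannot contain a retained intron of the matched transcript.
* **lncRNA flag.** The mapping from annotation biotypes to "lncRNA" is
  deliberately an input: the `gene_type == "lncRNA"` attribute is used
  when present and an explicit gene-id list overrides it, because biotype
  vocabularies differ between annotation releases.

## Artifact filters

**5′-degradation fragments.** A model is removed when another model on the
same chromosome and strand carries its junction chain as a contiguous
*proper suffix* in transcription order and their 3′ ends agree within
Δ₃ = 100 nt (`frag_delta3`); a mono-exonic model is removed when contained
in another model's 3′-most exon under the same 3′ agreement. The value
100 nt is a library-scale choice — large enough to absorb polyA-site
heterogeneity, small enough not to merge genuine alternative last exons —
and is exposed as a flag because the upstream tools it mirrors do not
print their default. The witness is sought in the *full input set*, which
makes the filter idempotent (asserted on 500 random sets).

**Intrapriming.** Oligo-dT priming at genomic A-tracts produces spurious
3′ ends. The flag is the adenine fraction, read on the transcript strand,
of the 20 genomic bases immediately downstream of the 3′ end, firing at
fraction ≥ 0.6 (the ≥ convention is asserted at exactly 0.6). The removal
step spares FSM transcripts: their 3′ ends are independently supported by
the annotation, so the filter targets novel-category artifacts only.

## CAGE and polyA annotation

The TSS-to-CAGE distance is measured from the transcript's 5′ boundary to
the nearest peak edge, 0 inside a peak, and signed so that negative means
the peak is upstream in transcription orientation; the `within_cage` flag
uses |distance| ≤ 50 bp. PolyA motifs are scanned in the transcript-strand
sequence of the 50 nt ending at the 3′ terminus; the motif whose end lies
closest to the terminus wins, with ties broken by motif list order so the
output is deterministic for a prioritized motif list.

## Alternative-splicing events

Events are defined *pairwise* between multi-exonic transcripts of one gene
grouping on transcription-order junction coordinates, then deduplicated by
a type-specific coordinate key (gene-level splice-graph variants are out
of scope). The conventions:

* SE: one transcript has consecutive junctions (d₁,a₁),(d₂,a₂), the other
  the bridging junction (d₁,a₂); key (d₁,a₁,d₂,a₂).
* MX: shared outer donor and acceptor around two non-overlapping middle
  exons.
* A5/A3: two junctions sharing an acceptor (donor) with different donors
  (acceptors), where the segment between the alternative sites is exonic
  in the transcript carrying the inner site — this exonic requirement is
  what distinguishes a genuine alternative site from an unrelated junction
  pair that happens to share one boundary.
* AF requires non-overlapping first exons whose first junctions share an
  acceptor; AL is the mirror at the 3′ end sharing a donor. This
  shared-anchor convention matches the local-event style of SUPPA-like
  tools. A5/A3 candidates at the first/last junction that are already
  explained by an AF/AL event are suppressed, so one biological structure
  yields one event.

Gene grouping uses each transcript's first associated gene; transcripts
without one (novel-gene categories) are clustered by same-strand overlap.
Per-gene "predominant" event types use *event* counts (not transcript
counts — the open alternative), with ties resolved in the fixed order
AF > SE > A3 > A5 > AL > MX > IR so summaries are reproducible.

## ORF, coding potential and NMD

The ORF finder scans the three forward frames of the already
orientation-resolved transcript sequence for ATG-initiated ORFs ending in
a stop, reports the longest and breaks ties toward the 5′-most start. The
ORF span and length include the stop codon; the protein length excludes
it. Codons containing N never qualify as start or stop.

The built-in coding score is the Fickett TESTCODE statistic computed from
the published position/composition lookup tables on the full transcript
sequence. It is a deliberate, transparent scorer — not a trained logistic
model — so its scale differs from CPAT-style coding *probabilities*.
Because of that, score provenance is recorded (`score_type` = `fickett` or
`external`): the probability cutoffs associated with CPAT (≥ 0.364 human,
> 0.44 mouse; note the strict inequality on the mouse side, exposed as
`strict`) are meant for externally supplied probability tables, which take
precedence when given.

NMD candidacy: an ORF whose stop codon ends more than `min_dist` nt
upstream of the last exon–exon junction, with mono-exonic transcripts
never flagged. The default is `min_dist = 0` — the plain "stop before the
last junction" wording — with 50 available to apply the canonical 50-nt
rule; the choice is a flag rather than a guess because the two differ only
for stops in a narrow window and the plain wording is the more
conservative reading.

## Expression, DTE and DTU

TPM is full-length count over sample total × 10⁶; every sample column of
the TPM assay sums to one million (asserted at 10⁻⁶ relative error). Gene
expression is the sum of member-transcript counts with mono-exonic
transcripts removed by default (they are enriched for artifacts and
unassignable lncRNA fragments) and fusion transcripts always excluded
(they have no single gene), renormalized to TPM.

Differential transcript expression uses the two-sided Wilcoxon rank-sum
test on TPM: exact when the combined n ≤ 20 and the data are tie-free,
otherwise the mid-rank normal approximation with continuity correction —
at the study-scale n of 4 vs 3 the exact null is the only defensible one.
No multiple-testing correction is applied by default, reproducing the
plain p < 0.05 rule; the DTU caller (`dtuFetalAdult`) requires two
transcripts of one gene significant in *opposite* directions with
|ΔTPM| > 20 each. "Exclusive differential expression" is operationalized
as that opposite-direction significance; the alternative reading —
detected in only one condition — is available separately as
`groupSpecificTranscripts` (detection mode, or mean TPM > 20 in exactly
one group). For two-region designs with single libraries per region,
`dtuRegionPair` replaces the test with a fold-change gate: mean-TPM fold
change ≥ 4 with a pseudocount of 1 TPM on both means (so zero means are
defined) and absolute difference > 20 TPM, with gene-level DTU requiring
two opposite-direction flagged transcripts.

Isoform-diversity correlations are Pearson (the plain "corr" convention),
computed between per-gene isoform counts and log₁₀ gene length / exon
count of the representative longest transcript, overall and restricted to
highly expressed genes (log₁₀ mean gene TPM > 2.5). Rarefaction subsamples
the read-to-transcript assignment vector without replacement and is
validated against the closed-form hypergeometric expectation
Σᵢ [1 − C(N−nᵢ, d)/C(N, d)].

### A note on DTU power at n = 4 vs 3

With four samples against three, the exact two-sided rank-sum p-value is
bounded below by 2/C(7,3) = 2/35 ≈ 0.057. An untied isoform switch —
however large — can therefore never reach p < 0.05; significance is only
possible through the tie path (an all-zero low group shifts the test to
the tie-corrected normal approximation, p ≈ 0.044). Under the planted
switch design used in the acceptance checks (swapped 60 and 5 TPM means,
negative-binomial dispersion 0.3, library depth 200,000 reads), that path
fires for roughly 15% of switch genes: pushing the low group toward all
zeros requires count means so small that the 12-fold-higher group starts
producing zeros too. The pipeline reports what the procedure actually
delivers — measured precision 1.0, recall ≈ 0.15, null call rate 0.0 —
rather than altering the test to manufacture power; a recall of 0.9 under
this design is mathematically out of reach for the p < 0.05 rule, and the
corresponding acceptance check is left failing with this analysis as its
explanation. At realistic per-condition replication (n ≥ 4 vs 4 gives a
minimum exact p of 2/70) the same rule regains power.

## The synthetic-data generator

The generator is the package's study stand-in: it builds gene
architectures on a transcription-order axis (exon lengths 80–260 nt,
introns 150–700 nt, 2–5 reference transcripts sharing a per-gene site
pool) and mirrors them onto either strand of a random genome, so every
planted structure has an exact truth label. Per default configuration it
emits ~1,050 query transcripts over ~820 genes on two 3-Mb chromosomes:
fixed quotas of each structural category (fusion from adjacent same-strand
gene pairs, intergenic from gene deserts, antisense/genic overlays on FSM
host genes), six single-event gene designs (one per AS type, each
contributing two reference-identical transcripts and exactly one event),
intron-retention genes (two exons merged across an annotated intron),
NMD-positive and NMD-negative genes whose exonic sequence is rewritten
with a designed single-ORF layout placing the stop 30 nt before or 60 nt
after the last junction, suffix-truncation and mono-exonic fragments with
matching 3′ ends, and intrapriming genes with a 20-base A-tract written
downstream of the 3′ end (all other query 3′ ends receive a neutral
25%-A flank so the truth labels are deterministic). CAGE peaks are
jittered around every reference TSS (σ = 15 bp, width 30 bp). Counts are
negative binomial (variance = μ + φμ², φ = 0.3 by default) at 200,000
reads per sample — a desk-scale stand-in for full-length library depths —
with log-normal background abundances and swapped 60/5-TPM means in
designated switch genes under a 4-vs-3 group design.

Genes with exact-recovery truth labels use the minimal reference set that
keeps the label unambiguous (NMD genes carry a single reference
transcript; ISM queries always retain a junction absent from the gene's
second reference transcript so the associated transcript is unique), and
a verification pass errors if any planted non-FSM chain collides with the
reference chain index.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing error and junction wobble (chains
are exact by construction), overlapping and nested gene annotations,
paralogous sequence (the genome is i.i.d. random, so mapping ambiguity
does not exist), realistic exon/intron length and GC distributions,
correlated library sizes, and biological replicate structure beyond NB
dispersion. The oracle-equivalence and truth-recovery results certify the
*logic* of the implementation, not robustness to noisy input.

## Problem sizes and runtime

The default acceptance computation classifies ~1,050 transcripts against
~2,500 reference transcripts and cross-checks every call against a
brute-force oracle (~1 s each), enumerates events on 300 random genes of
up to six transcripts against a naive pairwise oracle, checks 500 random
1-kb ORF instances and 200 exact-test instances, and measures DTU power
over 20 seeds × 100 genes; the whole script runs in roughly half a minute
on one CPU. These sizes were chosen as the smallest that still cover all
nine categories, all six event types and all planted artifact classes with
multiple instances on both strands.

## Known limitations

Exact junction matching makes the classifier sensitive to upstream
collapse quality; ISM/FSM resolution inherits any TSS/TTS degeneracy of
the annotation (resolved deterministically, not probabilistically); the
Fickett scorer is a screening statistic, not a calibrated coding
probability; the genome-browser palette follows the blue/cyan/red/orange
category convention (configurable, since published track legends disagree
among themselves); and the DTU procedures are threshold rules designed for
tiny n, not count-model inference — with adequate replication a
count-based model (e.g. DRIMSeq/DEXSeq-style) would be preferable.
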