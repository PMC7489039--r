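---
title: "Transcript structure analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript structure analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isostruct)
```

`isostruct` analyses full-length transcript models aligned to a genome, the
kind of data produced when PacBio Iso-Seq full-length non-chimeric (FLNC)
reads are mapped with a spliced aligner and summarised as exon-block
structures with an alignment percent identity (PID) and a read-support
count. This vignette explains the models behind each stage, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the design choices made where the underlying procedures are commonly
left under-specified.

## Coordinates, splice chains and overlap

All internal coordinates are 0-based half-open; GFF3/GTF I/O converts to and
from 1-based closed coordinates at the boundary. Half-open intervals make
overlap lengths exact differences and give touching exons overlap zero.

The structural identity of a multi-exon transcript is its **splice chain**:
the ordered internal exon boundaries, excluding the transcript's own start
and end. A $k$-exon transcript has $2(k-1)$ chain positions. Transcript
termini are deliberately excluded — long-read 5′/3′ ends vary with RNA
integrity and priming, so two reads with identical chains are the same
isoform regardless of how far their terminal exons extend. Single-exon
transcripts have an empty chain and are compared by exon overlap instead.

**Overlap fractions** divide the overlap length by the *shorter* feature's
length by default. The locus rule ("at least 20 % span overlap and more
than 20 % exon overlap") never states the denominator; the shorter-feature
reading is the most permissive and correctly merges short aligned fragments
into the locus of their full-length parent. A `policy = "reciprocal"`
option divides by the longer feature for users who want both fractions to
pass.

## Collapse: loci, isoform identity, redundancy rules

`assign_loci()` forms gene loci as connected components (single-linkage
closure) of the pairwise locus relation: same chromosome and strand, span
overlap ≥ 0.2, and at least one exon pair overlapping > 0.2. Component ids
are assigned deterministically (chromosome, then leftmost start, then
smallest member id), so locus naming is independent of input order.

`filter_redundant()` applies four rules in a fixed order; a transcript is
tagged with the first rule that removes it:

1. **degraded_5p** — the chain is a contiguous run of another member's
   chain and all missing sites lie on the candidate's 5′ side (genomic
   right on minus-strand transcripts). These are 5′-degraded copies, the
   dominant artefact of reverse transcription. *Exception*: when the
   candidate's 5′-terminal exon overlaps an intron of the containing model
   by ≥ 1 bp, it is retained — that configuration is a genuine
   intron-retention isoform whose unspliced terminal exon bridges the
   intron, not a degradation product.
2. **structure_subset** — the chain is a contiguous run of another chain
   with sites missing elsewhere. The same terminal-exon/intron exception is
   applied on each side where sites are missing; without it, an isoform
   retaining the *last* intron (whose chain is a prefix of the parent
   chain) would be destroyed by this rule, contradicting the intent of the
   exception. Non-contiguous sub-chains are *not* subsets: losing interior
   sites is the signature of exon skipping, which must survive as a genuine
   isoform. Single-exon transcripts (empty chain) are never subset victims
   — an empty site set carries no structural evidence — and are handled
   only by rule 4.
3. **low_pid_unsupported** — distinct chains whose best member PID is
   below 99 need corroboration: total FLNC support of at least 2 reads, or
   NGS (short-read) support/annotation on every junction. Support is summed
   FLNC reads across the input transcripts sharing the chain, since each
   aligned model may already represent several reads.
4. **duplicate_shorter** — among same-isoform members (identical chains,
   or overlapping single exons), the longest genomic span is kept, ties
   broken by lexicographic id; FLNC support of the merged duplicates is
   added to the representative, so total support is conserved.

Rules 1 and 2 are each run as a complete pass over all containing models
before the next rule, which keeps removal reasons well-defined when a chain
is simultaneously a 5′-aligned run of one isoform and an interior run of
another.

## Novelty against a reference

A collapsed locus is a **novel gene** when no annotated gene overlaps its
span by ≥ 20 % (reason `low_overlap`), or when every such overlap is on the
opposite strand (reason `antisense`). Otherwise it is matched to the
best-overlapping same-strand gene, and each isoform is tested: **novel**
iff its chain contains at least one site absent from the union of the
gene's annotated chains. The union (rather than per-transcript comparison)
is used because a site present in any annotated isoform is not new. The
single-exon blocking rule holds that a mono-exon read over a gene annotated
only with mono-exon transcripts can never be a novel isoform — the two
structures differ only in termini, which carry no splicing information.

The seven structural categories (`fusion_span` > `antisense` >
`novel_gene_intergenic` > `full_splice_match` > `incomplete_splice_match` >
`novel_isoform_known_gene` > `single_exon_overlap`) are assigned by that
fixed priority, so the scheme is a partition. The category vocabulary is
this package's own: multi-exon transcripts assembling known sites in a new
combination are grouped with `novel_isoform_known_gene` rather than given a
separate class.

## Alternative-splicing events

`enumerate_as_events()` compares all isoform pairs of a locus and emits
elementary events keyed by `(gene, mode, coordinates)` — isoform ids are
evidence, not identity, which makes event sets comparable across samples
whose isoform inventories differ.

* **IR / MIR**: an intron (or run of consecutive introns) of one isoform
  contained in a single exon of the other.
* **SKIP / MSKIP**: one or more internal exons of one isoform absent from
  the other while both flanking introns' outer splice sites are shared.
* **AE** with major type **AA**/**AD**: two introns sharing one boundary
  and differing at the other. The differing site is classified in
  transcript orientation — intron 3′ end = acceptor (AA), 5′ end = donor
  (AD) — so plus and minus strands map genomic left/right to donor/acceptor
  oppositely. Mirroring a locus's coordinates (without changing strand)
  therefore swaps AA and AD while leaving IR and ES counts fixed, a
  symmetry the test suite checks on every random locus.
* **AE / other**: transcript start/end shifts. These are terminal-exon-end
  differences, not internal splice-site choices, so they carry major type
  `other`; this is why the four major types sum to well under 100 % of all
  events in real data.

One disambiguation rule connects the classes: a boundary pair whose wider
intron fully contains an exon of the other isoform is *not* an AE event —
that configuration is exon skipping (the skip intron shares its donor with
one flanking intron and its acceptor with the other) and is already
reported as SKIP/MSKIP. Without this rule every skipping event would
spuriously generate one AA and one AD. Combination modes seen in
visualisations of such data (skipping plus an exon-end shift in the same
isoform, multiple alternative ends) are represented here as their
elementary constituents rather than as fused labels.

Events are deduplicated per locus by default; `dedup = FALSE` gives the
per-isoform-pair tally for users who want the alternative accounting.

`gate_by_expression()` keeps an event in a sample only when both witness
isoforms reach FPKM ≥ 0.01 (inclusive) in at least one biological
replicate. Sample comparison is exact set algebra on event keys:
`sample_specific_events()` returns the two difference sets and the shared
set with a gene-level rollup, and `call_dsgs()` defines a differentially
spliced gene as one whose event sets differ (non-empty symmetric
difference). Both definitions are set-theoretic reconstructions; the
procedures they stand in for are usually not specified more precisely than
this.

## Fusion transcripts

`detect_fusions()` consumes multi-segment alignments (the chimeric output
of a spliced aligner; this module does not re-align). Each segment of at
least 50 bp (a configurable noise guard) is assigned to the annotation
locus it passes the locus test against; segments on unannotated regions
receive provisional loci and still count. A transcript whose segments hit
two or more distinct loci is a fusion call — inter-chromosomal when the
segments span chromosomes, intra-chromosomal otherwise (requiring two
genuinely distinct loci prevents far-apart exons of one gene from being
miscalled). `support_filter()` partitions calls at ≥ 2 FLNC reads.

## Expression, DEGs, enrichment, qPCR

RPKM is `counts × 10⁹ / (gene length × library size)`; library sizes
default to column sums. The per-gene test is a two-sample t-test on
`log2(RPKM + 1)`. The **pooled-variance** (Student) form is the default: at
the typical 3-vs-3 replicate design the Welch approximation is markedly
conservative — its empirical size at nominal α = 0.05 is about 0.035 even
on exactly normal data, because the Satterthwaite degrees of freedom are
noisy at n = 3 — while the pooled test holds its level (0.050 on normal
data, ≈ 0.045–0.048 on negative-binomial simulations). `welch = TRUE`
restores the unequal-variance form. The pseudocount (default 1) and the
log base are exposed.

DEG calls apply three gates conjunctively: BH-adjusted FDR ≤ 0.05 (0.01 as
a stricter preset), |log₂ fold change| ≥ 2, and maximum group-mean
RPKM ≥ 0.1. The fold-change gate follows the methods-style reading
(|log₂FC| ≥ 2, i.e. 4-fold); the alternative fold-change-of-2 reading is
`min_abs_log2fc = 1`. The RPKM floor is applied to the larger group mean —
the permissive reading, since a gene silenced in one condition should
remain callable. `deg_set_algebra()` performs the cross-comparison
operations: pairwise intersections, and the candidate subtraction
(treatment-comparison DEGs minus control-comparison DEGs).

Enrichment is the upper-tail hypergeometric test per term with BH across
terms; `P(X ≥ k)` with `k` DE genes in the term, `K` background genes in
the term, `n` DE genes and `N` background genes. qPCR relative expression
is `2^−ΔΔCt` with ΔCt averaged over replicates and the calibrator sample
fixed at 1.

## The synthetic-data generator

`sim_config()` fixes the study conditions; every stage's test data flows
from it deterministically (fixed seed ⇒ byte-identical outputs, which the
suite verifies).

* **Reference**: genes laid out per chromosome with 2–8 kb intergenic
  gaps; exon counts 1 + Geometric (mean 5, capped at 12); exon lengths
  100–300 bp, introns 80–400 bp; 1–3 isoforms per gene, each extra isoform
  produced by a single splicing operator (intron retention, exon skip,
  alternative acceptor/donor with 10–60 bp shifts, terminal-end shift)
  whose event is recorded in the truth table using the same coordinate keys
  the classifier emits.
* **FLNC set**: an exact, NGS-supported copy of every reference transcript
  (PID ∈ [99, 100], support 1 + Poisson), plus per-gene corruptions at the
  configured rates, at most one corruption per gene so each transcript has
  exactly one primary truth label: 5′-degraded copies (leading exons
  removed on the transcript's 5′ side, strand-aware), interior structure
  subsets (verified at planting to align to no chain edge, so the expected
  removal reason is unambiguous), shorter same-chain duplicates, low-PID
  singletons (one perturbed splice site, support 1, the perturbed junction
  lacking NGS support), novel isoforms (a new splice site at high PID),
  intergenic novel genes, antisense transcripts, and two-segment fusion
  candidates.
* **Counts**: negative-binomial with gene-level means log-uniform in
  [20, 500], dispersion 0.05 (biological-replicate scale), per-sample
  library factors within 2× of each other, and a planted treatment effect
  (log₂FC magnitude 2–4, random sign) in a configurable fraction of genes
  over the 2-variety × 2-treatment × 3-replicate design with
  `<variety>-<treatment><replicate>` sample labels.

What the generator does **not** emulate: sequence content (no FASTQ, no
error models), alignment noise at exon boundaries (corruptions are
structural, not positional jitter), length-stratified library fractions,
GC/length expression bias, and stacked corruptions (one label per
transcript by design; a combination flag is deliberately absent so truth
stays unambiguous). Passing the planted-truth tests therefore demonstrates
that the *rules* are implemented correctly and identifiable under clean
conditions, not that the pipeline is robust to alignment artefacts of real
long-read data.

## Test and verification sizes

The suite checks the collapse labels on 20 simulated FLNC sets of 200
genes each; event enumeration against an independent naive classifier
(every intron/exon containment and boundary pair, written loop-by-loop) on
500 random loci of ≤ 4 isoforms and ≤ 6 exons, plus the mirror symmetry on
each; BH against a brute-force step-up on 1,000 random p-vectors; the
hypergeometric tail against exhaustive enumeration of all subsets for every
(N ≤ 12, K, n, k); the null type-I error on 10,000 negative-binomial genes;
and DEG sensitivity on planted |log₂FC| = 3 at means ≥ 200 and dispersion
0.02 — "adequate counts", i.e. the regime where a 3-vs-3 design has power;
at biological dispersion 0.05 and means down to 50 the same test tops out
near 91 % sensitivity, a power limit of the design rather than an
implementation property.

## Known limitations

* The locus relation is single-linkage, so one promiscuous fragment can
  chain otherwise distinct loci; real pipelines inherit the same behaviour.
* AA/AD classification assumes a known strand; strand-unknown loci are
  classified under a plus-strand convention with a warning.
* The DEG engine is the described t-test, not a count-model test; with few
  replicates a negative-binomial GLM (edgeR/DESeq2 style) has better power
  at low counts, and the module is structured so such an engine could be
  swapped in behind `deg_test()`.
* `compare_to_truth()` scores identity of calls, not breakpoint accuracy;
  fusion segments are taken as aligned, so chimera detection upstream is
  out of scope.
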