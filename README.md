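# isostruct

Transcript-structure analysis for hybrid long-read transcriptomes.

Full-length single-molecule sequencing (PacBio Iso-Seq) yields complete
transcript models, but the raw full-length non-chimeric (FLNC) reads are
redundant and error-prone: a gene is observed through many overlapping
copies, 5′-degraded fragments, low-identity alignments and duplicated
structures. `isostruct` implements the downstream structural analysis for
such data once the reads have been aligned to a genome:

* **Collapse** — group aligned FLNC transcript models into gene loci
  (single-linkage over a "≥ 20 % span overlap and > 20 % exon overlap, same
  strand" rule) and reduce each locus to non-redundant isoforms. Isoform
  identity is *splice-chain* identity: the ordered internal splice sites,
  excluding the transcript start and end. Redundancy removal follows three
  ordered rules: drop 5′-degraded copies (contiguous 3′ sub-chains, unless
  the candidate's 5′ exon spans an intron of the fuller model — those are
  genuine intron-retention isoforms); drop contiguous structure subsets;
  require chains with alignment identity (PID) < 99 to carry ≥ 2 FLNC reads
  or fully NGS-supported junctions; keep the longest copy of each isoform.
* **Novelty** — classify collapsed loci against a reference annotation.
  A locus is a novel gene when it overlaps no annotated gene by ≥ 20 %, or
  only antisense; an isoform of a known gene is novel when it carries ≥ 1
  splice site absent from all annotated isoforms (with a single-exon
  blocking rule). Every transcript also receives one of seven structural
  categories (full/incomplete splice match, novel isoform, intergenic,
  antisense, fusion span, single-exon overlap).
* **Alternative splicing** — enumerate events between the isoforms of each
  locus: intron retention (IR/MIR), exon skipping (SKIP/MSKIP) and
  alternative exon ends (AE), the last classified in transcript orientation
  as alternative acceptor (AA, intron 3′ end) or donor (AD, intron 5′ end).
  Events are gated by isoform expression (FPKM ≥ 0.01 in any replicate),
  compared across samples, and rolled up into differentially spliced genes
  (DSGs).
* **Fusions** — transcripts whose aligned segments occupy ≥ 2 distinct loci,
  categorised inter- vs intra-chromosomal and partitioned by FLNC support
  (≥ 2 reads = well supported).
* **Expression** — RPKM (`counts · 10⁹ / (length · library size)`), per-gene
  two-sample t-tests on log₂(RPKM + 1), Benjamini–Hochberg FDR, the DEG
  gates RPKM ≥ 0.1, |log₂FC| ≥ 2, FDR ≤ 0.05, DEG set algebra across
  comparisons, hypergeometric (upper-tail) enrichment and qPCR 2^–ΔΔCt
  relative expression.
* **Synthetic data** — a generator that plants all of the above with
  machine-readable truth: reference annotations with alternatively spliced
  isoforms, FLNC sets with labelled corruptions, fusion segment pairs, and
  negative-binomial count matrices with planted log₂ fold changes over a
  2-variety × 2-treatment × 3-replicate design.

## Worked example

```r
library(isostruct)

cfg <- sim_config(seed = 3, n_genes = 60)
run <- run_pipeline(cfg)
run$summary
#>             stage   n
#> 1            loci  65
#> 2        isoforms 104
#> 3 novel_gene_loci   5
#> 4  novel_isoforms   3
#> 5       as_events  43
#> 6    fusion_calls   2
#> 7            degs   5
```

The 60 simulated genes yield 104 surviving isoforms in 65 loci after
collapse (the extra loci are the planted novel genes, antisense transcripts
and fusion partners); 5 loci are called novel genes, 3 isoforms carry new
splice sites, 43 AS events are enumerated, both planted fusions are found,
and 5 of the 6 planted DE genes pass the DEG gates (one planted fold change
sits near the |log₂FC| ≥ 2 boundary at this noise level). Because the generator records its ground
truth, the whole run can be scored:

```r
compare_to_truth(run)
#>                          class n_truth n_predicted precision recall f1
#> 1          removed_degraded_5p       6           6         1      1  1
#> 2     removed_structure_subset       6           6         1      1  1
#> 3  removed_low_pid_unsupported       3           3         1      1  1
#> 4    removed_duplicate_shorter       6           6         1      1  1
#> 5                         kept     104         104         1      1  1
#> 6       novel_gene_transcripts       5           5         1      1  1
#> 7               novel_isoforms       3           3         1      1  1
#> 8                       fusion       2           2         1      1  1
#> ...
```

Individual stages are plain functions over plain objects —
`read_annotation()`, `collapse_transcripts()`, `classify_novelty()`,
`enumerate_as_events()`, `detect_fusions()`, `rpkm()`, `deg_test()`,
`call_degs()`, `hypergeom_enrich()`, `delta_delta_ct()` — see the vignette
in `vignettes/transcript-structure.Rmd` for the models and parameter
choices.

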