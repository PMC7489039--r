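test_that("same_locus applies the 20% span + >20% exon overlap rule", {
  t1 <- tm("a", 100, 500)
  t2 <- tm("b", 400, 900)
  expect_true(same_locus(t1, t2))         # span 0.25 >= 0.2, exon 0.25 > 0.2
  expect_true(same_locus(t1, t1))
  expect_false(same_locus(t1, tm("c", 400, 900, strand = "-")))
  expect_false(same_locus(t1, tm("d", 400, 900, chrom = "chr2")))
  # span bound is inclusive (>= 0.2) but the exon bound is strict (> 0.2)
  t5 <- tm("e", 0, 500)
  t6 <- tm("f", 400, 900)
  expect_false(same_locus(t5, t6))        # both fractions exactly 0.2
})

test_that("same_isoform compares splice chains, not terminal ends", {
  a <- tm("a", c(0, 200), c(100, 300))
  b <- tm("b", c(50, 200), c(100, 280))   # same chain, different termini
  expect_true(same_isoform(a, b))
  expect_false(same_isoform(a, tm("c", c(0, 210), c(100, 300))))
  expect_true(same_isoform(tm("d", 0, 500), tm("e", 400, 900)))
  expect_false(same_isoform(tm("f", 0, 500), a))  # mixed single/multi
  expect_false(same_isoform(tm("g", 0, 100), tm("h", 100, 200)))
})

test_that("assign_loci takes the transitive closure of overlaps", {
  A <- tm("A", 0, 1000)
  B <- tm("B", 750, 1750)
  C <- tm("C", 1500, 2500)   # overlaps B, disjoint from A
  m <- assign_loci(list(A, B, C))
  expect_length(unique(m), 1L)
  m2 <- assign_loci(list(tm("x", 0, 500), tm("y", 0, 500, chrom = "chr2")))
  expect_length(unique(m2), 2L)
})

test_that("assign_loci is invariant under input permutation", {
  set.seed(31)
  cfg <- sim_config(seed = 31, n_genes = 25)
  flnc <- simulate_flnc(simulate_reference(cfg), cfg)
  txs <- flnc$transcripts
  m1 <- assign_loci(txs)
  m2 <- assign_loci(txs[sample(length(txs))])
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("filter_redundant removes 5'-degraded suffix chains", {
  X <- tm("X", c(0, 200, 400, 600), c(100, 300, 500, 700))
  Y <- tm("Y", c(420, 600), c(500, 700))  # chain [500,600] = X's 3' run
  fr <- filter_redundant(list(X, Y))
  expect_equal(fr$removed[["Y"]], "degraded_5p")
  # on the minus strand the same structure is a 3' truncation -> subset rule
  Xm <- tm("Xm", c(0, 200, 400, 600), c(100, 300, 500, 700), strand = "-")
  Ym <- tm("Ym", c(420, 600), c(500, 700), strand = "-")
  frm <- filter_redundant(list(Xm, Ym))
  expect_equal(frm$removed[["Ym"]], "structure_subset")
})

test_that("an IR candidate spanning the missing intron is retained", {
  X <- tm("X", c(0, 200, 400), c(100, 300, 500))
  # chain suffix of X but its 5' exon bridges X's first intron: retained
  Y <- tm("Y", c(50, 400), c(300, 500))
  fr <- filter_redundant(list(X, Y))
  expect_setequal(fr$kept, c("X", "Y"))
})

test_that("interior sub-chains are removed as structure subsets", {
  X <- tm("X", c(0, 200, 400, 600), c(100, 300, 500, 700))
  Y <- tm("Y", c(200, 400), c(300, 500))  # interior exons 2..3
  fr <- filter_redundant(list(X, Y))
  expect_equal(fr$removed[["Y"]], "structure_subset")
  # a non-contiguous subset (exon-skipping pattern) must survive
  Z <- tm("Z", c(0, 400), c(100, 500))    # skips exon 2: sites {100, 400}
  fr2 <- filter_redundant(list(X, Z))
  expect_setequal(fr2$kept, c("X", "Z"))
})

test_that("low-PID chains need two reads or full NGS junction support", {
  lone <- tm("L1", c(0, 200), c(100, 300), pid = 97.5,
             flnc_support = 1L, ngs_support = FALSE)
  expect_equal(filter_redundant(list(lone))$removed[["L1"]],
               "low_pid_unsupported")
  supported <- tm("L2", c(0, 200), c(100, 300), pid = 97.5,
                  flnc_support = 1L, ngs_support = TRUE)
  expect_setequal(filter_redundant(list(supported))$kept, "L2")
  two_reads <- tm("L3", c(0, 200), c(100, 300), pid = 97.5,
                  flnc_support = 2L, ngs_support = FALSE)
  expect_setequal(filter_redundant(list(two_reads))$kept, "L3")
  high_pid <- tm("L4", c(0, 200), c(100, 300), pid = 99.3,
                 flnc_support = 1L, ngs_support = FALSE)
  expect_setequal(filter_redundant(list(high_pid))$kept, "L4")
})

test_that("among identical chains the longest span wins", {
  long <- tm("longer", c(0, 200), c(100, 1200))
  short <- tm("short", c(50, 200), c(100, 1000))
  fr <- filter_redundant(list(short, long))
  expect_equal(fr$removed[["short"]], "duplicate_shorter")
  # ties broken lexicographically
  a <- tm("aa", c(0, 200), c(100, 300))
  b <- tm("bb", c(0, 200), c(100, 300))
  expect_setequal(filter_redundant(list(b, a))$kept, "aa")
})

test_that("collapse keeps one representative per isoform and sums support", {
  a <- tm("a", c(0, 200), c(100, 320), flnc_support = 2L)
  b <- tm("b", c(40, 200), c(100, 300), flnc_support = 3L)
  res <- collapse_transcripts(list(a, b))
  expect_equal(n_transcripts(res$annotation), 1L)
  kept <- annotation_transcripts(res$annotation)[[1]]
  expect_equal(kept$id, "a")
  expect_equal(kept$flnc_support, 5L)
})

test_that("collapse of an empty input is empty", {
  res <- collapse_transcripts(list())
  expect_equal(n_loci(res$annotation), 0L)
  expect_equal(nrow(res$report), 0L)
})

test_that("collapse is idempotent and permutation invariant", {
  cfg <- sim_config(seed = 12, n_genes = 40)
  flnc <- simulate_flnc(simulate_reference(cfg), cfg)
  res1 <- collapse_transcripts(flnc$transcripts)
  # idempotence: collapsing the collapsed set changes nothing
  res2 <- collapse_transcripts(annotation_transcripts(res1$annotation))
  expect_equal(n_transcripts(res2$annotation), n_transcripts(res1$annotation))
  expect_true(all(res2$report$status == "kept"))
  # permutation invariance
  set.seed(99)
  shuffled <- flnc$transcripts[sample(length(flnc$transcripts))]
  res3 <- collapse_transcripts(shuffled)
  expect_identical(res3$report[order(res3$report$transcript_id), ],
                   res1$report[order(res1$report$transcript_id), ])
})

test_that("no surviving pair is the same isoform and support is conserved", {
  cfg <- sim_config(seed = 13, n_genes = 40)
  flnc <- simulate_flnc(simulate_reference(cfg), cfg)
  res <- collapse_transcripts(flnc$transcripts)
  for (l in res$annotation$loci) {
    txs <- l$transcripts
    if (length(txs) < 2) next
    for (i in seq_along(txs)) for (j in seq_along(txs)) {
      if (i < j) expect_false(same_isoform(txs[[i]], txs[[j]]),
                              info = paste(l$id, txs[[i]]$id, txs[[j]]$id))
    }
  }
  total_in <- sum(vapply(flnc$transcripts, `[[`, 0L, "flnc_support"))
  kept_ids <- res$report$transcript_id[res$report$status == "kept"]
  dup_ids <- res$report$transcript_id[res$report$status == "removed" &
                                      res$report$reason == "duplicate_shorter"]
  other_removed <- setdiff(res$report$transcript_id, c(kept_ids, dup_ids))
  total_out <- sum(vapply(annotation_transcripts(res$annotation),
                          `[[`, 0L, "flnc_support")) +
    sum(vapply(flnc$transcripts[other_removed], `[[`, 0L, "flnc_support"))
  expect_equal(total_out, total_in)
})

test_that("a noise-free FLNC set collapses to the reference isoform count", {
  cfg <- sim_config(seed = 14, n_genes = 30, degraded_rate = 0,
                    subset_rate = 0, low_pid_rate = 0, duplicate_rate = 0,
                    novel_isoform_rate = 0, novel_gene_rate = 0,
                    antisense_rate = 0, fusion_rate = 0)
  ref <- simulate_reference(cfg)
  flnc <- simulate_flnc(ref, cfg)
  res <- collapse_transcripts(flnc$transcripts)
  expect_equal(n_transcripts(res$annotation), n_transcripts(ref$annotation))
  expect_equal(n_loci(res$annotation), n_loci(ref$annotation))
})

test_that("planted corruption labels are recovered exactly", {
  cfg <- sim_config(seed = 15, n_genes = 100)
  flnc <- simulate_flnc(simulate_reference(cfg), cfg)
  res <- collapse_transcripts(flnc$transcripts)
  truth <- flnc$truth[flnc$truth$label != "fusion", ]
  m <- merge(truth, res$report, by.x = "id", by.y = "transcript_id")
  expect_equal(nrow(m), nrow(truth))
  pred <- ifelse(m$status == "kept", "kept", m$reason)
  expect_identical(pred, m$expected)
})
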