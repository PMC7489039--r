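test_that("intron retention is detected with the retaining isoform as carrier", {
  loc <- gene_locus("g", list(tm("A", c(0, 300), c(200, 500)),
                              tm("B", 0, 500)))
  ev <- enumerate_as_events(loc)
  ir <- ev[ev$major_type == "IR", ]
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$mode, "IR")
  expect_equal(ir$coords, "200-300")
  expect_equal(ir$isoform_in, "B")
  expect_equal(ir$isoform_out, "A")
})

test_that("multiple consecutive retained introns collapse into one MIR event", {
  loc <- gene_locus("g", list(
    tm("A", c(0, 300, 600), c(200, 500, 800)),
    tm("B", 0, 800)))
  ev <- enumerate_as_events(loc)
  expect_equal(ev$mode[ev$major_type == "IR"], "MIR")
  expect_equal(ev$coords[ev$major_type == "IR"], "200-300,500-600")
})

test_that("exon skipping requires shared outer splice sites", {
  loc <- gene_locus("g", list(
    tm("A", c(0, 200, 400), c(100, 300, 500)),
    tm("B", c(0, 400), c(100, 500))))
  ev <- enumerate_as_events(loc)
  es <- ev[ev$major_type == "ES", ]
  expect_equal(es$mode, "SKIP")
  expect_equal(es$coords, "200-300")
  expect_equal(es$isoform_in, "A")
  expect_equal(es$isoform_out, "B")
  # without a shared downstream site there is no skipping event
  loc2 <- gene_locus("g2", list(
    tm("A", c(0, 200, 400), c(100, 300, 500)),
    tm("B", c(0, 420), c(100, 500))))
  expect_equal(sum(enumerate_as_events(loc2)$major_type == "ES"), 0L)
})

test_that("AA/AD classification follows transcript orientation", {
  plus <- gene_locus("g", list(
    tm("A", c(0, 200), c(100, 300)),
    tm("B", c(0, 250), c(100, 300))))
  ev <- enumerate_as_events(plus)
  internal <- ev[ev$major_type %in% c("AA", "AD"), ]
  expect_equal(internal$major_type, "AA")   # shared donor 100, acceptors differ
  expect_equal(internal$coords, "200-250")
  minus <- gene_locus("g", list(
    tm("A", c(0, 200), c(100, 300), strand = "-"),
    tm("B", c(0, 250), c(100, 300), strand = "-")))
  evm <- enumerate_as_events(minus)
  expect_equal(evm$major_type[evm$major_type %in% c("AA", "AD")], "AD")
})

test_that("terminal end shifts are AE events of major type other", {
  loc <- gene_locus("g", list(tm("A", c(0, 200), c(100, 300)),
                              tm("B", c(20, 200), c(100, 300))))
  ev <- enumerate_as_events(loc)
  expect_equal(ev$mode, "AE")
  expect_equal(ev$major_type, "other")
  expect_equal(ev$coords, "0-20")
  expect_equal(nrow(enumerate_as_events(loc, terminal_ae = FALSE)), 0L)
})

test_that("single-isoform loci yield no events", {
  loc <- gene_locus("g", list(tm("A", c(0, 200), c(100, 300))))
  expect_equal(nrow(enumerate_as_events(loc)), 0L)
})

test_that("event sets are invariant to isoform input order", {
  set.seed(51)
  for (i in 1:25) {
    loc <- random_locus(sprintf("g%02d", i))
    perm <- gene_locus(loc$id, sample(loc$transcripts))
    expect_identical(event_key_set(enumerate_as_events(perm)),
                     event_key_set(enumerate_as_events(loc)))
  }
})

test_that("enumerate_as_events matches the naive oracle on random loci", {
  set.seed(52)
  for (i in 1:120) {
    loc <- random_locus(sprintf("g%03d", i))
    expect_identical(event_key_set(enumerate_as_events(loc)),
                     oracle_as_events(loc), info = loc$id)
  }
})

test_that("mirroring coordinates swaps AA and AD and fixes IR/ES", {
  set.seed(53)
  for (i in 1:60) {
    loc <- random_locus(sprintf("g%03d", i))
    ev <- enumerate_as_events(loc)
    evm <- enumerate_as_events(mirror_locus(loc))
    tab <- function(e) table(factor(e$major_type,
                                    c("AA", "AD", "IR", "ES", "other")))
    t1 <- tab(ev); t2 <- tab(evm)
    expect_equal(unname(t2[["AA"]]), unname(t1[["AD"]]), info = loc$id)
    expect_equal(unname(t2[["AD"]]), unname(t1[["AA"]]), info = loc$id)
    expect_equal(unname(t2[["IR"]]), unname(t1[["IR"]]), info = loc$id)
    expect_equal(unname(t2[["ES"]]), unname(t1[["ES"]]), info = loc$id)
  }
})

test_that("planted AS events are recovered exactly in forced runs", {
  for (op in c("retain_intron", "skip_exon", "alt_acceptor", "alt_donor",
               "alt_exon_end")) {
    probs <- setNames(rep(0, 5), c("retain_intron", "skip_exon",
                                   "alt_acceptor", "alt_donor",
                                   "alt_exon_end"))
    probs[op] <- 1
    cfg <- sim_config(seed = 54, n_genes = 30,
                      isoforms_per_gene = c(2L, 2L), as_probs = probs)
    ref <- simulate_reference(cfg)
    got <- enumerate_annotation_events(ref$annotation)
    want <- ref$truth$events
    expect_setequal(paste(got$gene, got$mode, got$major_type, got$coords),
                    paste(want$gene, want$mode, want$major_type, want$coords))
  }
})

test_that("the expression gate keeps events only when both isoforms pass", {
  loc <- gene_locus("g", list(tm("A", c(0, 300), c(200, 500)),
                              tm("B", 0, 500)))
  ev <- enumerate_as_events(loc)
  fpkm <- rbind(A = c(0.01, 0, 5, 5), B = c(0.3, 0.2, 0, 0))
  colnames(fpkm) <- c("s1r1", "s1r2", "s2r1", "s2r2")
  sets <- gate_by_expression(ev, fpkm, c("s1", "s1", "s2", "s2"))
  expect_equal(nrow(sets$s1), nrow(ev))   # 0.01 in one replicate passes
  expect_equal(nrow(sets$s2), 0L)         # B silent in s2
  # threshold 0 keeps everything present in the table
  sets0 <- gate_by_expression(ev, fpkm, c("s1", "s1", "s2", "s2"),
                              threshold = 0)
  expect_equal(nrow(sets0$s2), nrow(ev))
  expect_error(gate_by_expression(ev, fpkm[1, , drop = FALSE],
                                  c("s1", "s1", "s2", "s2")), "missing")
})

test_that("type percentages are computed against all events", {
  sets <- list(s1 = data.frame(gene = "g", mode = c("IR", "IR", "SKIP", "AE"),
                               major_type = c("IR", "IR", "ES", "AA"),
                               coords = c("1-2", "3-4", "5-6", "7-8"),
                               stringsAsFactors = FALSE))
  sm <- summarize_types(sets)
  expect_equal(sm$IR, 50)
  expect_equal(sm$ES, 25)
  expect_equal(sm$AA, 25)
  expect_equal(sm$AD, 0)
  expect_warning(summarize_types(list(empty = sets$s1[0, ])), "no AS events")
})

test_that("sample-specific events and DSG calls are exact set operations", {
  ev <- function(gene, mode, coords)
    data.frame(gene = gene, mode = mode, major_type = "IR", coords = coords,
               stringsAsFactors = FALSE)
  A <- rbind(ev("g1", "IR", "1-2"), ev("g2", "SKIP", "3-4"))
  B <- ev("g1", "IR", "1-2")
  sp <- sample_specific_events(A, B)
  expect_equal(nrow(sp$only_a), 1L)
  expect_equal(nrow(sp$only_b), 0L)
  expect_equal(nrow(sp$shared), 1L)
  expect_equal(sp$genes_specific_a, "g2")
  dsg <- call_dsgs(A, B)
  expect_equal(dsg$gene, "g2")
  expect_equal(dsg$modes, "SKIP")
  expect_equal(nrow(call_dsgs(A, A)), 0L)
  # disjoint sets: everything is specific
  C <- rbind(ev("g3", "IR", "9-10"), ev("g4", "IR", "11-12"))
  sp2 <- sample_specific_events(A, C)
  expect_equal(c(nrow(sp2$only_a), nrow(sp2$only_b), nrow(sp2$shared)),
               c(2L, 2L, 0L))
})

test_that("condition-specific planted events give the planted DSG list", {
  cfg <- sim_config(seed = 55, n_genes = 20, isoforms_per_gene = c(2L, 2L),
                    as_probs = c(retain_intron = 1, skip_exon = 0,
                                 alt_acceptor = 0, alt_donor = 0,
                                 alt_exon_end = 0))
  ref <- simulate_reference(cfg)
  all_ev <- enumerate_annotation_events(ref$annotation)
  # sample A expresses everything; in sample B half the genes lose their
  # second isoform, so their events disappear
  genes <- unique(all_ev$gene)
  lost <- genes[seq_len(floor(length(genes) / 2))]
  B <- all_ev[!(all_ev$gene %in% lost), , drop = FALSE]
  dsg <- call_dsgs(all_ev, B)
  expect_setequal(dsg$gene, lost)
})
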