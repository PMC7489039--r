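toy_em <- function(counts, lengths = NULL, libs = NULL) {
  if (is.null(lengths)) lengths <- setNames(rep(1000, nrow(counts)),
                                            rownames(counts))
  em <- expression_matrix(counts, lengths,
                          data.frame(sample = colnames(counts)),
                          library_sizes = if (is.null(libs)) colSums(counts)
                                          else libs)
  em
}

test_that("RPKM reproduces its closed form and scaling laws", {
  counts <- matrix(10L, 1, 1, dimnames = list("g", "s"))
  em <- toy_em(counts, c(g = 1000), libs = 1e6)
  expect_equal(unname(rpkm(em)["g", "s"]), 10)
  expect_equal(unname(rpkm(toy_em(matrix(0L, 1, 1,
    dimnames = list("g", "s")), c(g = 1000), libs = 1e6))[1, 1]), 0)
  # doubling the library halves the column
  em2 <- toy_em(counts, c(g = 1000), libs = 2e6)
  expect_equal(rpkm(em2), rpkm(em) / 2)
  # joint scaling of counts and library sizes is invariant
  set.seed(7)
  counts3 <- matrix(rpois(30, 50), 10, 3,
                    dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  em3 <- toy_em(counts3)
  em4 <- toy_em(counts3 * 4L, libs = colSums(counts3) * 4)
  expect_equal(rpkm(em4), rpkm(em3))
  em0 <- toy_em(counts, c(g = 1000), libs = 1e6)
  em0$library_sizes[1] <- 0
  expect_error(rpkm(em0), "zero library")
})

test_that("deg_test handles null and degenerate inputs", {
  counts <- matrix(rep(c(32L, 8L), each = 3), 1, byrow = TRUE,
                   dimnames = list("g", paste0("s", 1:6)))
  em <- toy_em(counts, libs = rep(1e6, 6))
  # identical replicate vectors in both groups
  same <- toy_em(matrix(20L, 1, 6, dimnames = list("g", paste0("s", 1:6))),
                 libs = rep(1e6, 6))
  st0 <- deg_test(same, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(st0$log2fc, 0)
  expect_equal(st0$p_value, 1)
  # constant but different groups: forced fold change, degenerate p
  st <- deg_test(em, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(st$degenerate)
  expect_equal(st$p_value, 0)
  expect_gt(st$log2fc, 0)
  # agreement with stats::t.test on non-degenerate data
  set.seed(17)
  counts2 <- matrix(rpois(600, 80), 100, 6,
                    dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  em2 <- toy_em(counts2)
  st2 <- deg_test(em2, paste0("s", 1:3), paste0("s", 4:6))
  x <- log2(rpkm(em2) + 1)
  ref_p <- apply(x, 1, function(r)
    stats::t.test(r[1:3], r[4:6], var.equal = TRUE)$p.value)
  expect_equal(st2$p_value, unname(ref_p), tolerance = 1e-12)
  st2w <- deg_test(em2, paste0("s", 1:3), paste0("s", 4:6), welch = TRUE)
  ref_pw <- apply(x, 1, function(r) stats::t.test(r[1:3], r[4:6])$p.value)
  expect_equal(st2w$p_value, unname(ref_pw), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-computed example and brute force", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(23)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), brute_force_bh(p), info = i)
  }
})

test_that("DEG gates are conjunctive with sign-directed calls", {
  st <- data.frame(gene = c("up", "weak_fc", "weak_fdr", "low_expr"),
                   log2fc = c(2.5, 1.5, 3, 4),
                   mean_rpkm_a = c(5, 5, 5, 0.01),
                   mean_rpkm_b = c(0.5, 1, 0.2, 0.001),
                   p_value = c(0.0001, 0.0001, 0.9, 0.0001),
                   stringsAsFactors = FALSE)
  out <- call_degs(st)
  expect_equal(out$call, c("up", "not_de", "not_de", "not_de"))
  down <- call_degs(data.frame(gene = "d", log2fc = -3, mean_rpkm_a = 0.01,
                               mean_rpkm_b = 5, p_value = 1e-6))
  expect_equal(down$call, "down")
})

test_that("planted DE genes are recovered with high sensitivity", {
  # adequate counts: means >= 200 and replicate-level dispersion 0.02
  # (about 15% CV), the regime where a 3 vs 3 design has power
  hits <- 0; total <- 0
  for (seed in 1:5) {
    set.seed(seed)
    n <- 2000
    mu <- exp(runif(n, log(200), log(2000)))
    lfc <- rep(0, n)
    de <- sample(n, 100)
    lfc[de] <- sample(c(-3, 3), 100, replace = TRUE)
    counts <- sapply(1:6, function(s) {
      eff <- if (s <= 3) 2^lfc else rep(1, n)
      rnbinom(n, mu = mu * eff, size = 1 / 0.02)
    })
    dimnames(counts) <- list(paste0("g", 1:n), paste0("s", 1:6))
    em <- toy_em(counts)
    st <- deg_test(em, paste0("s", 1:3), paste0("s", 4:6))
    out <- call_degs(st)
    hits <- hits + sum(out$call[de] != "not_de")
    total <- total + length(de)
  }
  expect_gte(hits / total, 0.95)
})

test_that("DEG set algebra reproduces shared and candidate sets", {
  res <- deg_set_algebra(list(v1 = c("a", "b", "c"), v2 = c("b", "c", "d")))
  expect_equal(res$pairwise$n_shared, 2L)
  expect_equal(res$pairwise$shared, "b,c")
  res2 <- deg_set_algebra(list(T_cmp = c("x", "y", "z"), CK_cmp = "y"),
                          treatment_comparison = "T_cmp",
                          control_comparison = "CK_cmp")
  expect_equal(res2$shared_t_ck, "y")
  expect_setequal(res2$candidates, c("x", "z"))
  res3 <- deg_set_algebra(list(a = c("p", "q"), b = c("r", "s")))
  expect_equal(res3$pairwise$n_shared, 0L)
  # order-invariant and idempotent
  res4 <- deg_set_algebra(list(v2 = c("d", "c", "b", "c"),
                               v1 = c("c", "b", "a")))
  expect_equal(res4$pairwise$n_shared, res$pairwise$n_shared)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  res <- hypergeom_enrich(c("g1", "g2"), paste0("g", 1:4),
                          list(tm1 = c("g1", "g2")))
  expect_equal(res$p_value, 1 / 6, tolerance = 1e-12)
  # term covering the whole background, and an empty intersection
  res2 <- hypergeom_enrich(c("g1", "g2"), paste0("g", 1:6),
                           list(all = paste0("g", 1:6),
                                none = c("g5", "g6")))
  expect_equal(res2$p_value[res2$term == "all"], 1)
  expect_equal(res2$p_value[res2$term == "none"], 1)
  expect_error(hypergeom_enrich("zz", paste0("g", 1:4), list(t = "g1")),
               "absent from background")
  set.seed(29)
  for (i in 1:10) {
    N <- sample(6:10, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    de <- paste0("g", sample(N, n)); bg <- paste0("g", 1:N)
    term <- list(t = paste0("g", seq_len(K)))
    k <- length(intersect(de, term$t))
    expect_equal(hypergeom_enrich(de, bg, term)$p_value,
                 enum_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("2^-ddCt reproduces its closed forms", {
  ct <- data.frame(gene = "g", sample = c("trt", "trt", "cal", "cal"),
                   replicate = c(1, 2, 1, 2),
                   ct_target = c(22, 22, 24, 24),
                   ct_reference = c(20, 20, 21, 21))
  out <- delta_delta_ct(ct, "cal")
  expect_equal(out$rel_expr[out$sample == "trt"], 2)   # ddCt = 2 - 3 = -1
  expect_equal(out$rel_expr[out$sample == "cal"], 1)
  # replicate dCt identical to the calibrator: ratio 1, no dispersion
  ct2 <- data.frame(gene = "g", sample = c("a", "a", "a", "cal"),
                    replicate = c(1, 2, 3, 1),
                    ct_target = c(25, 25, 25, 25),
                    ct_reference = c(23, 23, 23, 23))
  out2 <- delta_delta_ct(ct2, "cal")
  expect_equal(out2$rel_expr, c(1, 1))
  ct_bad <- ct; ct_bad$ct_reference[1] <- NA
  expect_error(delta_delta_ct(ct_bad, "cal"), "reference")
  expect_error(delta_delta_ct(ct, "nope"), "calibrator")
})
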