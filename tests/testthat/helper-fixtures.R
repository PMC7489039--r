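# shorthand transcript constructor: tm("id", starts, ends)
tm <- function(id, starts, ends, chrom = "chr1", strand = "+", ...) {
  transcript_model(id, chrom, strand, cbind(starts, ends), ...)
}

# random multi-isoform locus for oracle tests: a base gene of up to
# `max_exons` exons plus up to `max_iso` isoforms derived by random
# structural edits (intron retention, exon drop, boundary shift, end trim)
random_locus <- function(id, max_iso = 4, max_exons = 6, strand = NULL) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  k <- sample(2:max_exons, 1)
  exon_w <- sample(80:200, k, replace = TRUE)
  intron_w <- sample(60:200, k - 1, replace = TRUE)
  starts <- 1000 + c(0, cumsum(exon_w[-k] + intron_w))
  E <- cbind(starts, starts + exon_w)
  txs <- list(transcript_model(paste0(id, ".t1"), "chr1", strand, E))
  n_iso <- sample(2:max_iso, 1)
  for (j in 2:n_iso) {
    E2 <- E
    for (edit in seq_len(sample(1:2, 1))) {
      kk <- nrow(E2)
      op <- sample(c("merge", "drop", "shift", "trim"), 1)
      if (op == "merge" && kk >= 2) {
        q <- sample(kk - 1, 1)
        E2 <- rbind(E2[seq_len(q - 1), , drop = FALSE],
                    c(E2[q, 1], E2[q + 1, 2]),
                    E2[-seq_len(q + 1), , drop = FALSE])
      } else if (op == "drop" && kk >= 3) {
        E2 <- E2[-sample(2:(kk - 1), 1), , drop = FALSE]
      } else if (op == "shift" && kk >= 2) {
        q <- sample(kk - 1, 1)
        side <- sample(c(1, 2), 1)
        if (side == 1) {
          lo <- E2[q, 1] + 20; hi <- E2[q + 1, 1] - 10
          if (lo < hi) E2[q, 2] <- sample(lo:hi, 1)
        } else {
          lo <- E2[q, 2] + 10; hi <- E2[q + 1, 2] - 20
          if (lo < hi) E2[q + 1, 1] <- sample(lo:hi, 1)
        }
      } else if (op == "trim") {
        w <- E2[1, 2] - E2[1, 1]
        if (w > 60) E2[1, 1] <- E2[1, 1] + sample(10:40, 1)
      }
    }
    txs[[j]] <- transcript_model(paste0(id, ".t", j), "chr1", strand, E2)
  }
  # drop same-chain duplicates so the locus is a set of distinct isoforms
  keys <- vapply(txs, function(t) paste(splice_chain(t), collapse = ","), "")
  keys <- paste(keys, vapply(txs, function(t) nrow(t$exons) == 1, TRUE))
  gene_locus(id, txs[!duplicated(keys)])
}

# naive reference classifier for AS events: every (intron, exon) containment
# and every intron boundary pair, loop by loop, no early exits -- used as the
# independent oracle for enumerate_as_events
oracle_as_events <- function(locus) {
  txs <- locus$transcripts
  strand <- locus$strand
  out <- list()
  push <- function(mode, major, coords) {
    out[[length(out) + 1]] <<- c(mode = mode, major = major, coords = coords)
  }
  fmt <- function(m) paste(apply(matrix(m, ncol = 2), 1, function(r)
    paste0(format(r[1], scientific = FALSE, trim = TRUE), "-",
           format(r[2], scientific = FALSE, trim = TRUE))), collapse = ",")
  ids <- names(txs)
  for (ai in ids) for (bi in ids) {
    if (ai == bi) next
    A <- txs[[ai]]; B <- txs[[bi]]
    nA <- nrow(A$exons); nB <- nrow(B$exons)
    intrA <- if (nA > 1) cbind(A$exons[-nA, 2], A$exons[-1, 1]) else
      matrix(0, 0, 2)
    intrB <- if (nB > 1) cbind(B$exons[-nB, 2], B$exons[-1, 1]) else
      matrix(0, 0, 2)
    # retained introns of A inside exons of B, grouped per retaining exon
    # into maximal consecutive runs
    for (e in seq_len(nB)) {
      contained <- integer(0)
      for (q in seq_len(nrow(intrA))) {
        if (B$exons[e, 1] <= intrA[q, 1] && B$exons[e, 2] >= intrA[q, 2])
          contained <- c(contained, q)
      }
      while (length(contained)) {
        run <- contained[1]
        while (length(contained) > length(run) &&
               contained[length(run) + 1] == run[length(run)] + 1)
          run <- c(run, contained[length(run) + 1])
        contained <- contained[-seq_along(run)]
        push(if (length(run) > 1) "MIR" else "IR", "IR",
             fmt(intrA[run, , drop = FALSE]))
      }
    }
    # exons of A skipped relative to an intron of B with shared outer sites
    chainA <- splice_chain(A)
    for (q in seq_len(nrow(intrB))) {
      d <- intrB[q, 1]; acc <- intrB[q, 2]
      if (!any(chainA == d) || !any(chainA == acc)) next
      inside <- integer(0)
      for (e in seq_len(nA)) {
        if (A$exons[e, 1] > d && A$exons[e, 2] < acc) inside <- c(inside, e)
      }
      if (length(inside))
        push(if (length(inside) > 1) "MSKIP" else "SKIP", "ES",
             fmt(A$exons[inside, , drop = FALSE]))
    }
    # intron boundary pairs sharing exactly one site; a pair whose wider
    # intron engulfs a complete exon of either isoform is a skipping
    # pattern, not an exon-end choice
    if (ai < bi) {
      engulfs <- function(lo, hi) {
        hit <- FALSE
        for (e in seq_len(nA))
          if (A$exons[e, 1] > lo && A$exons[e, 2] < hi) hit <- TRUE
        for (e in seq_len(nB))
          if (B$exons[e, 1] > lo && B$exons[e, 2] < hi) hit <- TRUE
        hit
      }
      for (q in seq_len(nrow(intrA))) for (r in seq_len(nrow(intrB))) {
        if (intrA[q, 1] == intrB[r, 1] && intrA[q, 2] != intrB[r, 2] &&
            !engulfs(intrA[q, 1], max(intrA[q, 2], intrB[r, 2]))) {
          push("AE", if (strand == "-") "AD" else "AA",
               fmt(c(min(intrA[q, 2], intrB[r, 2]),
                     max(intrA[q, 2], intrB[r, 2]))))
        }
        if (intrA[q, 2] == intrB[r, 2] && intrA[q, 1] != intrB[r, 1] &&
            !engulfs(min(intrA[q, 1], intrB[r, 1]), intrA[q, 2])) {
          push("AE", if (strand == "-") "AA" else "AD",
               fmt(c(min(intrA[q, 1], intrB[r, 1]),
                     max(intrA[q, 1], intrB[r, 1]))))
        }
      }
      sA <- A$exons[1, 1]; sB <- B$exons[1, 1]
      if (sA != sB) push("AE", "other", fmt(c(min(sA, sB), max(sA, sB))))
      eA <- A$exons[nA, 2]; eB <- B$exons[nB, 2]
      if (eA != eB) push("AE", "other", fmt(c(min(eA, eB), max(eA, eB))))
    }
  }
  if (!length(out)) return(character(0))
  sort(unique(vapply(out, paste, "", collapse = "|")))
}

# canonical event-key set of an enumerate_as_events result
event_key_set <- function(ev) {
  if (is.null(ev) || nrow(ev) == 0) return(character(0))
  sort(unique(paste(ev$mode, ev$major_type, ev$coords, sep = "|")))
}

# mirror a locus: x -> M - x on every exon boundary, same strand
mirror_locus <- function(locus, M = NULL) {
  if (is.null(M))
    M <- max(vapply(locus$transcripts, function(t) t$exons[nrow(t$exons), 2], 0)) + 1000
  txs <- lapply(locus$transcripts, function(t) {
    E <- t$exons
    E2 <- cbind(rev(M - E[, 2]), rev(M - E[, 1]))
    transcript_model(t$id, t$chrom, t$strand, E2, pid = t$pid,
                     flnc_support = t$flnc_support)
  })
  gene_locus(locus$id, txs)
}

# brute-force Benjamini-Hochberg step-up from its defining formula:
# adj_i = min over observed thresholds t >= p_i of  n * t / #(p <= t)
brute_force_bh <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) n * t / sum(p <= t), 0)))
  }, 0)
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# n-subsets of a background of size N with K marked elements
enum_hyper_tail <- function(N, K, n, k) {
  marked <- seq_len(K)
  hits <- 0; total <- 0
  sets <- utils::combn(N, n)
  for (i in seq_len(ncol(sets))) {
    total <- total + 1
    if (sum(sets[, i] %in% marked) >= k) hits <- hits + 1
  }
  hits / total
}
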