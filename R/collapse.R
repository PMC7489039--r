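#' Do two transcript models belong to the same gene locus?
#'
#' Two transcripts share a locus when they lie on the same chromosome and
#' strand, their genomic spans overlap by at least `min_span_overlap` of the
#' shorter span, and at least one exon pair (one exon from each transcript)
#' overlaps by more than `min_exon_overlap` of the shorter exon.
#'
#' @param t1,t2 `transcript_model` objects.
#' @param min_span_overlap Span-overlap fraction threshold (inclusive);
#'   default 0.2.
#' @param min_exon_overlap Exon-overlap fraction threshold (exclusive);
#'   default 0.2.
#' @param policy Overlap denominator policy, see [overlap_fraction()].
#' @return `TRUE` or `FALSE`.
#' @export
same_locus <- function(t1, t2, min_span_overlap = 0.2, min_exon_overlap = 0.2,
                       policy = "shorter") {
  if (t1$chrom != t2$chrom || t1$strand != t2$strand) return(FALSE)
  if (t1$strand == "*") {
    warning("strand-unknown transcript excluded from locus test: ", t1$id)
    return(FALSE)
  }
  if (overlap_fraction(tx_span(t1), tx_span(t2), policy) < min_span_overlap)
    return(FALSE)
  for (i in seq_len(nrow(t1$exons))) {
    a <- t1$exons[i, ]
    for (j in seq_len(nrow(t2$exons))) {
      if (overlap_fraction(a, t2$exons[j, ], policy) > min_exon_overlap)
        return(TRUE)
    }
  }
  FALSE
}

#' Are two transcripts the same isoform?
#'
#' Single-exon transcripts of one locus are the same isoform when their exons
#' overlap; multi-exon transcripts are the same isoform when their splice
#' chains are identical (terminal exon ends are ignored, as the structure
#' excludes initiation and termination sites). A single-exon and a multi-exon
#' transcript are never the same isoform.
#'
#' @param t1,t2 `transcript_model` objects assumed to share a locus.
#' @return `TRUE` or `FALSE`.
#' @export
same_isoform <- function(t1, t2) {
  k1 <- n_exons(t1); k2 <- n_exons(t2)
  if (k1 == 1L && k2 == 1L)
    return(interval_overlap(t1$exons[1L, ], t2$exons[1L, ]) > 0)
  if (k1 == 1L || k2 == 1L) return(FALSE)
  c1 <- splice_chain(t1); c2 <- splice_chain(t2)
  length(c1) == length(c2) && all(c1 == c2)
}

#' Group transcripts into gene loci
#'
#' Loci are the connected components of the [same_locus()] relation
#' (single-linkage transitive closure): if A overlaps B and B overlaps C, all
#' three share one locus even when A and C are disjoint. Locus identifiers
#' are deterministic -- components are ordered by chromosome, then leftmost
#' start, then the lexicographically smallest member transcript id -- so the
#' result is invariant under permutation of the input.
#'
#' @param transcripts List of `transcript_model`.
#' @inheritParams same_locus
#' @param id_prefix Prefix for generated locus ids.
#' @return Named character vector: transcript id -> locus id.
#' @export
assign_loci <- function(transcripts, min_span_overlap = 0.2,
                        min_exon_overlap = 0.2, policy = "shorter",
                        id_prefix = "LOC") {
  n <- length(transcripts)
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  ids <- vapply(transcripts, `[[`, "", "id")
  names(transcripts) <- ids

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }

  key <- paste(vapply(transcripts, `[[`, "", "chrom"),
               vapply(transcripts, `[[`, "", "strand"))
  starts <- vapply(transcripts, tx_start, 0)
  ends <- vapply(transcripts, tx_end, 0)
  for (g in split(seq_len(n), key)) {
    g <- g[order(starts[g])]
    for (a in seq_along(g)) {
      i <- g[a]
      for (b in seq_along(g)[-seq_len(a)]) {
        j <- g[b]
        if (starts[j] >= ends[i]) break  # sorted sweep: no later span overlaps
        if (same_locus(transcripts[[i]], transcripts[[j]], min_span_overlap,
                       min_exon_overlap, policy))
          union2(i, j)
      }
    }
  }

  comp <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), comp)
  ord <- order(vapply(groups, function(g) transcripts[[g[1]]]$chrom, ""),
               vapply(groups, function(g) min(starts[g]), 0),
               vapply(groups, function(g) min(ids[g]), ""))
  groups <- groups[ord]
  lid <- sprintf("%s%05d", id_prefix, seq_along(groups))
  out <- character(n)
  for (k in seq_along(groups)) out[groups[[k]]] <- lid[k]
  stats::setNames(out, ids)
}

# is `short` a contiguous run inside `long`? (strict: short shorter than long)
# returns 0 when not; otherwise the 1-based start index of the match
chain_run_index <- function(short, long) {
  ns <- length(short); nl <- length(long)
  if (ns == 0L || ns >= nl) return(0L)
  for (s in seq_len(nl - ns + 1L)) {
    if (all(long[s:(s + ns - 1L)] == short)) return(s)
  }
  0L
}

# does the candidate's terminal exon on the given side ("left"/"right",
# genomic) overlap any intron of the containing model by >= 1 bp?
terminal_exon_spans_intron <- function(cand, container, side) {
  ex <- if (side == "left") cand$exons[1L, ] else cand$exons[nrow(cand$exons), ]
  ints <- introns(container)
  if (nrow(ints) == 0L) return(FALSE)
  any(apply(ints, 1L, function(iv) interval_overlap(ex, iv) > 0))
}

#' Remove redundant and false-positive transcript structures within a locus
#'
#' Applies, in order, the redundancy/false-positive rules used to clean a
#' locus's FLNC transcript models:
#' \enumerate{
#'   \item \strong{degraded_5p} -- a transcript whose splice chain is a
#'     contiguous run of another member's chain with the missing sites on its
#'     5' side (a 5'-degraded copy) is removed, \emph{unless} its 5'-terminal
#'     exon spans an intron of the containing model, in which case it is
#'     retained as a genuine intron-retention candidate.
#'   \item \strong{structure_subset} -- a transcript whose chain is a
#'     contiguous run of another member's chain (missing sites elsewhere) is
#'     removed, with the same terminal-exon/intron-retention exception on the
#'     side(s) where sites are missing.
#'   \item \strong{low_pid_unsupported} -- for each surviving distinct splice
#'     chain whose best member PID is below `pid_threshold`, the chain is
#'     kept only when its summed FLNC support is at least
#'     `min_support_low_pid` or every junction is NGS-annotated/supported.
#'   \item \strong{duplicate_shorter} -- among transcripts that are the same
#'     isoform, only the one with the longest genomic span survives (ties
#'     broken by lexicographic id).
#' }
#' Each removed transcript is tagged with the first matching reason.
#' Non-contiguous sub-chains are \emph{not} subsets: losing interior sites is
#' the signature of exon skipping, a genuine isoform, not of degradation.
#' Single-exon transcripts carry no splice sites and are therefore never
#' subset victims; they are deduplicated by exon overlap in step 4.
#'
#' @param locus A `gene_locus` (or plain list of `transcript_model` sharing
#'   chromosome and strand).
#' @param pid_threshold PID below which a chain needs extra support
#'   (default 99).
#' @param min_support_low_pid Minimum summed FLNC support for a low-PID chain
#'   (default 2).
#' @return A list with `kept` (character vector of transcript ids) and
#'   `removed` (named character vector: transcript id -> reason).
#' @export
filter_redundant <- function(locus, pid_threshold = 99,
                             min_support_low_pid = 2) {
  txs <- if (inherits(locus, "gene_locus")) locus$transcripts else locus
  ids <- vapply(txs, `[[`, "", "id")
  names(txs) <- ids
  n <- length(txs)
  removed <- character(0)
  dup_of <- character(0)
  alive <- rep(TRUE, n)
  chains <- lapply(txs, splice_chain)
  strand <- if (n) txs[[1L]]$strand else "+"

  # steps 1 & 2: contiguous sub-chain removal. The degraded-5' rule is a
  # complete pass over all container transcripts before the subset rule runs,
  # so each transcript gets the first matching reason in rule order.
  run_info <- function(i, j) {
    s <- chain_run_index(chains[[i]], chains[[j]])
    if (s == 0L) return(NULL)
    list(at_start = s == 1L,
         at_end = s + length(chains[[i]]) - 1L == length(chains[[j]]))
  }
  for (i in seq_len(n)) {
    if (length(chains[[i]]) == 0L) next
    for (j in seq_len(n)) {
      if (i == j) next
      ri <- run_info(i, j)
      if (is.null(ri)) next
      # missing sites only on the transcript's 5' side
      missing_5p <- if (strand == "+") ri$at_end && !ri$at_start
                    else ri$at_start && !ri$at_end
      if (!missing_5p) next
      side5 <- if (strand == "+") "left" else "right"
      if (terminal_exon_spans_intron(txs[[i]], txs[[j]], side5)) next
      alive[i] <- FALSE
      removed[ids[i]] <- "degraded_5p"
      break
    }
  }
  for (i in seq_len(n)) {
    if (!alive[i] || length(chains[[i]]) == 0L) next
    for (j in seq_len(n)) {
      if (i == j) next
      ri <- run_info(i, j)
      if (is.null(ri)) next
      missing_5p <- if (strand == "+") ri$at_end && !ri$at_start
                    else ri$at_start && !ri$at_end
      if (missing_5p) next  # handled (or excepted) by the degraded-5' pass
      # intron-retention exception on each side where sites are missing
      spans <- (!ri$at_start &&
                terminal_exon_spans_intron(txs[[i]], txs[[j]], "left")) ||
               (!ri$at_end &&
                terminal_exon_spans_intron(txs[[i]], txs[[j]], "right"))
      if (spans) next
      alive[i] <- FALSE
      removed[ids[i]] <- "structure_subset"
      break
    }
  }

  # step 3: low-PID chains need >= min support or full NGS junction support
  if (any(alive)) {
    key <- vapply(chains, paste, "", collapse = ",")
    for (k in unique(key[alive])) {
      if (k == "") next  # single-exon: no junctions to doubt
      members <- which(alive & key == k)
      max_pid <- max(vapply(txs[members], `[[`, 0, "pid"))
      if (max_pid >= pid_threshold) next
      support <- sum(vapply(txs[members], `[[`, 0L, "flnc_support"))
      ngs_ok <- any(vapply(txs[members],
                           function(t) all(t$ngs_support), TRUE))
      if (support >= min_support_low_pid || ngs_ok) next
      alive[members] <- FALSE
      removed[ids[members]] <- "low_pid_unsupported"
    }
  }

  # step 4: among same-isoform duplicates keep the longest span
  surv <- which(alive)
  if (length(surv) > 1L) {
    # connected components of same_isoform among survivors
    comp <- seq_along(surv)
    for (a in seq_along(surv)) for (b in seq_along(surv)) {
      if (a >= b) next
      if (same_isoform(txs[[surv[a]]], txs[[surv[b]]]))
        comp[comp == comp[b]] <- comp[a]
    }
    for (g in split(surv, comp)) {
      if (length(g) < 2L) next
      spans <- vapply(txs[g], tx_span_length, 0)
      keep <- g[order(-spans, ids[g])][1L]
      drop <- setdiff(g, keep)
      alive[drop] <- FALSE
      removed[ids[drop]] <- "duplicate_shorter"
      dup_of[ids[drop]] <- ids[keep]
    }
  }

  list(kept = ids[alive], removed = removed, dup_of = dup_of)
}

#' Collapse FLNC transcript models into a non-redundant annotation
#'
#' Composes [assign_loci()], per-locus [filter_redundant()] and isoform
#' deduplication into the full cleaning step: the output annotation contains
#' one representative transcript per surviving isoform, with FLNC support
#' summed over the duplicates merged into each representative.
#'
#' @param transcripts List of `transcript_model` (the aligned FLNC set).
#' @inheritParams same_locus
#' @inheritParams filter_redundant
#' @param id_prefix Prefix for locus ids.
#' @return A list with components `annotation` (the collapsed
#'   [annotation()]) and `report` (data frame with columns `transcript_id`,
#'   `locus_id`, `status`, `reason`).
#' @examples
#' a <- transcript_model("a", "chr1", "+", cbind(c(0, 200), c(100, 300)))
#' b <- transcript_model("b", "chr1", "+", cbind(c(10, 200), c(100, 290)))
#' res <- collapse_transcripts(list(a, b))
#' res$report
#' @export
collapse_transcripts <- function(transcripts, min_span_overlap = 0.2,
                                 min_exon_overlap = 0.2, policy = "shorter",
                                 pid_threshold = 99, min_support_low_pid = 2,
                                 id_prefix = "LOC") {
  if (length(transcripts) == 0L) {
    return(list(annotation = annotation(),
                report = data.frame(transcript_id = character(0),
                                    locus_id = character(0),
                                    status = character(0),
                                    reason = character(0))))
  }
  ids <- vapply(transcripts, `[[`, "", "id")
  names(transcripts) <- ids
  loci_map <- assign_loci(transcripts, min_span_overlap, min_exon_overlap,
                          policy, id_prefix)
  status <- stats::setNames(rep("kept", length(ids)), ids)
  reason <- stats::setNames(rep(NA_character_, length(ids)), ids)

  loci <- list()
  for (lid in sort(unique(loci_map))) {
    member_ids <- names(loci_map)[loci_map == lid]
    members <- transcripts[sort(member_ids)]
    fr <- filter_redundant(members, pid_threshold, min_support_low_pid)
    status[names(fr$removed)] <- "removed"
    reason[names(fr$removed)] <- fr$removed
    if (!length(fr$kept)) next
    reps <- members[fr$kept]
    # fold the FLNC support of merged duplicates into their representative
    for (d in names(fr$dup_of)) {
      r <- fr$dup_of[[d]]
      reps[[r]]$flnc_support <- reps[[r]]$flnc_support +
        members[[d]]$flnc_support
    }
    loci[[lid]] <- gene_locus(lid, reps)
  }

  report <- data.frame(transcript_id = ids,
                       locus_id = unname(loci_map[ids]),
                       status = unname(status[ids]),
                       reason = unname(reason[ids]),
                       stringsAsFactors = FALSE)
  report <- report[order(report$transcript_id), , drop = FALSE]
  rownames(report) <- NULL
  list(annotation = annotation(unname(loci)), report = report)
}
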