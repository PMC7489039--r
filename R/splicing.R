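# canonical string form of event coordinates: "start-end[,start-end...]"
coord_key <- function(m) {
  m <- matrix(m, ncol = 2)
  paste(apply(m, 1L, function(r)
    paste0(format(r[1L], scientific = FALSE, trim = TRUE), "-",
           format(r[2L], scientific = FALSE, trim = TRUE))), collapse = ",")
}

#' Enumerate alternative-splicing events among a locus's isoforms
#'
#' All isoform pairs of the locus are compared structurally and every
#' elementary splicing difference is emitted:
#' \itemize{
#'   \item \strong{IR / MIR} -- an intron (or a run of consecutive introns)
#'     of one isoform is fully contained in a single exon of the other
#'     (intron retention; major type `IR`). `isoform_in` is the isoform whose
#'     exon retains the intron.
#'   \item \strong{SKIP / MSKIP} -- one (or several consecutive) internal
#'     exon(s) of one isoform are absent from the other while both flanking
#'     introns' outer splice sites are shared (exon skipping; major type
#'     `ES`). `isoform_in` is the isoform containing the exon(s).
#'   \item \strong{AE} -- two introns, one from each isoform, share one
#'     boundary and differ at the other (alternative exon end). The differing
#'     site is classified in transcript orientation: at the intron's 3' end
#'     it is an alternative acceptor (major type `AA`), at the 5' end an
#'     alternative donor (`AD`). On the minus strand the genomic left/right
#'     roles are therefore swapped.
#'   \item \strong{AE at transcript termini} -- isoform pairs whose
#'     transcript start or end coordinates differ are emitted as mode `AE`
#'     with major type `other`: terminal-exon-end shifts are not internal
#'     splice-site choices, which is why the four major types account for
#'     only part of all events.
#' }
#'
#' Event identity is `(gene, mode, coordinates)`; isoform ids are evidence,
#' not identity, so events found in several isoform pairs are deduplicated by
#' default (set `dedup = FALSE` for the per-pair tally).
#'
#' @param locus A `gene_locus` with at least 2 isoforms (fewer yields an
#'   empty table).
#' @param dedup Deduplicate events across isoform pairs (default `TRUE`).
#' @param terminal_ae Also emit transcript start/end shifts as `AE`/`other`
#'   events (default `TRUE`).
#' @return Data frame with columns `gene`, `mode`, `major_type`, `coords`,
#'   `shared_site`, `isoform_in`, `isoform_out`.
#' @export
enumerate_as_events <- function(locus, dedup = TRUE, terminal_ae = TRUE) {
  txs <- locus$transcripts
  gene <- locus$id
  strand <- locus$strand
  if (strand == "*")
    warning("locus ", gene, " has unknown strand; AA/AD orientation assumes '+'")
  empty <- data.frame(gene = character(0), mode = character(0),
                      major_type = character(0), coords = character(0),
                      shared_site = numeric(0), isoform_in = character(0),
                      isoform_out = character(0), stringsAsFactors = FALSE)
  if (length(txs) < 2L) return(empty)

  rows <- list()
  emit <- function(mode, major, coords, shared, iin, iout) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, mode = mode, major_type = major, coords = coords,
      shared_site = shared, isoform_in = iin, isoform_out = iout,
      stringsAsFactors = FALSE)
  }

  ids <- sort(names(txs))
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a == b) next
    A <- txs[[ids[a]]]; B <- txs[[ids[b]]]
    iA <- introns(A); iB <- introns(B)
    cA <- splice_chain(A)

    # intron retention: introns of A contained in an exon of B,
    # grouped by retaining exon into IR (1 intron) or MIR (>= 2)
    if (nrow(iA) > 0L) {
      host <- rep(NA_integer_, nrow(iA))
      for (q in seq_len(nrow(iA))) {
        for (e in seq_len(nrow(B$exons))) {
          if (B$exons[e, "start"] <= iA[q, "start"] &&
              B$exons[e, "end"] >= iA[q, "end"]) { host[q] <- e; break }
        }
      }
      for (e in unique(host[!is.na(host)])) {
        qs <- which(host == e)
        # consecutive runs of retained introns within one exon
        runs <- split(qs, cumsum(c(1, diff(qs) != 1)))
        for (r in runs) {
          emit(if (length(r) > 1L) "MIR" else "IR", "IR",
               coord_key(iA[r, , drop = FALSE]), NA, B$id, A$id)
        }
      }
    }

    # exon skipping: an intron of B whose outer sites are splice sites of A,
    # with >= 1 internal exon of A strictly inside it
    if (nrow(iB) > 0L && length(cA) > 0L) {
      for (q in seq_len(nrow(iB))) {
        d <- iB[q, "start"]; acp <- iB[q, "end"]
        if (!(d %in% cA) || !(acp %in% cA)) next
        inside <- which(A$exons[, "start"] > d & A$exons[, "end"] < acp)
        if (!length(inside)) next
        emit(if (length(inside) > 1L) "MSKIP" else "SKIP", "ES",
             coord_key(A$exons[inside, , drop = FALSE]), NA, A$id, B$id)
      }
    }

    # alternative exon ends at internal splice sites (AA / AD). A boundary
    # pair is only an exon-end choice when the wider intron does not swallow
    # a complete exon of the other isoform -- that pattern is exon skipping
    # and is reported as SKIP/MSKIP, not as AA/AD.
    if (a < b && nrow(iA) > 0L && nrow(iB) > 0L) {
      exon_within <- function(lo, hi) {
        any(A$exons[, "start"] > lo & A$exons[, "end"] < hi) ||
          any(B$exons[, "start"] > lo & B$exons[, "end"] < hi)
      }
      for (q in seq_len(nrow(iA))) for (r in seq_len(nrow(iB))) {
        sL1 <- iA[q, "start"]; sR1 <- iA[q, "end"]
        sL2 <- iB[r, "start"]; sR2 <- iB[r, "end"]
        if (sL1 == sL2 && sR1 != sR2) {
          if (exon_within(sL1, max(sR1, sR2))) next
          # shared genomic-left boundary, differing right: the differing site
          # is the acceptor on '+', the donor on '-'
          major <- if (strand == "-") "AD" else "AA"
          emit("AE", major, coord_key(cbind(min(sR1, sR2), max(sR1, sR2))),
               sL1, A$id, B$id)
        } else if (sR1 == sR2 && sL1 != sL2) {
          if (exon_within(min(sL1, sL2), sR1)) next
          major <- if (strand == "-") "AA" else "AD"
          emit("AE", major, coord_key(cbind(min(sL1, sL2), max(sL1, sL2))),
               sR1, A$id, B$id)
        }
      }
    }

    # terminal exon-end shifts (transcript start/end), major type "other"
    if (terminal_ae && a < b) {
      if (tx_start(A) != tx_start(B))
        emit("AE", "other",
             coord_key(cbind(min(tx_start(A), tx_start(B)),
                             max(tx_start(A), tx_start(B)))), NA, A$id, B$id)
      if (tx_end(A) != tx_end(B))
        emit("AE", "other",
             coord_key(cbind(min(tx_end(A), tx_end(B)),
                             max(tx_end(A), tx_end(B)))), NA, A$id, B$id)
    }
  }

  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (dedup) {
    key <- paste(out$mode, out$major_type, out$coords)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out <- out[order(out$mode, out$coords), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate AS events for every locus of an annotation
#'
#' @param ann An [annotation()].
#' @inheritParams enumerate_as_events
#' @return Combined event data frame (see [enumerate_as_events()]).
#' @export
enumerate_annotation_events <- function(ann, dedup = TRUE, terminal_ae = TRUE) {
  rbind_rows(lapply(ann$loci, enumerate_as_events, dedup = dedup,
                    terminal_ae = terminal_ae),
             enumerate_as_events(gene_locus("empty", list(
               transcript_model("none", "chr0", "+", cbind(0, 1))))))
}

event_keys <- function(events) paste(events$gene, events$mode, events$coords)

#' Gate AS events by isoform expression
#'
#' An event is retained for a sample when both of its witness isoforms reach
#' `threshold` FPKM (inclusive) in at least one biological replicate of that
#' sample.
#'
#' @param events Event data frame from [enumerate_as_events()].
#' @param fpkm Numeric matrix, isoforms x replicates (rownames are isoform
#'   ids).
#' @param replicate_sample Character vector mapping each `fpkm` column to its
#'   sample label (length `ncol(fpkm)`).
#' @param threshold FPKM threshold, default 0.01.
#' @return Named list of per-sample event data frames (a `sample_event_set`).
#' @export
gate_by_expression <- function(events, fpkm, replicate_sample,
                               threshold = 0.01) {
  stopifnot(length(replicate_sample) == ncol(fpkm))
  need <- unique(c(events$isoform_in, events$isoform_out))
  miss <- setdiff(need, rownames(fpkm))
  if (length(miss))
    stop("isoforms missing from FPKM table: ", paste(miss, collapse = ", "))
  out <- list()
  for (s in unique(replicate_sample)) {
    cols <- which(replicate_sample == s)
    best <- apply(fpkm[, cols, drop = FALSE], 1L, max)
    keep <- best[events$isoform_in] >= threshold &
            best[events$isoform_out] >= threshold
    out[[s]] <- events[keep, , drop = FALSE]
  }
  out
}

#' Per-sample percentages of the four major AS types
#'
#' Percentages of `AA`, `IR`, `AD` and `ES` events are computed against
#' \emph{all} events of the sample, including terminal-end `other` events, so
#' the four types need not sum to 100.
#'
#' @param event_sets Named list of per-sample event data frames.
#' @return Data frame with columns `sample`, `n_events`, `AA`, `IR`, `AD`,
#'   `ES` (percentages).
#' @export
summarize_types <- function(event_sets) {
  rows <- lapply(names(event_sets), function(s) {
    ev <- event_sets[[s]]
    n <- nrow(ev)
    if (n == 0L) {
      warning("sample ", s, " has no AS events; percentages set to 0")
      pct <- c(AA = 0, IR = 0, AD = 0, ES = 0)
    } else {
      pct <- 100 * vapply(c(AA = "AA", IR = "IR", AD = "AD", ES = "ES"),
                          function(m) sum(ev$major_type == m) / n, 0)
    }
    data.frame(sample = s, n_events = n, AA = pct[["AA"]], IR = pct[["IR"]],
               AD = pct[["AD"]], ES = pct[["ES"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Sample-specific and shared AS events
#'
#' Exact set difference/intersection on event keys `(gene, mode, coords)`,
#' with a gene-level rollup: a gene is specific to a sample when it has at
#' least one event found only in that sample.
#'
#' @param set_a,set_b Event data frames for the two samples.
#' @return List with `only_a`, `only_b`, `shared` (event data frames) and
#'   `genes_specific_a`, `genes_specific_b` (character vectors).
#' @export
sample_specific_events <- function(set_a, set_b) {
  ka <- event_keys(set_a); kb <- event_keys(set_b)
  only_a <- set_a[!(ka %in% kb), , drop = FALSE]
  only_b <- set_b[!(kb %in% ka), , drop = FALSE]
  shared <- set_a[ka %in% kb, , drop = FALSE]
  list(only_a = only_a, only_b = only_b, shared = shared,
       genes_specific_a = sort(unique(only_a$gene)),
       genes_specific_b = sort(unique(only_b$gene)))
}

#' Call differentially spliced genes (DSGs) between two samples
#'
#' A gene is differentially spliced when its event sets differ between the
#' two samples (non-empty symmetric difference of event keys).
#'
#' @param set_a,set_b Event data frames for the two samples.
#' @return Data frame with columns `gene` and `modes` (comma-separated modes
#'   driving the call), sorted by gene id.
#' @export
call_dsgs <- function(set_a, set_b) {
  ka <- event_keys(set_a); kb <- event_keys(set_b)
  diff_a <- set_a[!(ka %in% kb), , drop = FALSE]
  diff_b <- set_b[!(kb %in% ka), , drop = FALSE]
  d <- rbind(diff_a, diff_b)
  if (nrow(d) == 0L)
    return(data.frame(gene = character(0), modes = character(0),
                      stringsAsFactors = FALSE))
  modes <- vapply(split(d$mode, d$gene),
                  function(m) paste(sort(unique(m)), collapse = ","), "")
  out <- data.frame(gene = names(modes), modes = unname(modes),
                    stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}
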