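#' Classify a gene locus as novel or known against a reference annotation
#'
#' A locus is a \strong{novel gene} when (1) it overlaps no annotated gene,
#' or overlaps every overlapping annotated gene by less than
#' `min_gene_overlap` (reason `low_overlap`), or (2) overlap of at least
#' `min_gene_overlap` exists only with genes on the opposite strand (reason
#' `antisense`). Otherwise it is known and matched to the best-overlapping
#' same-strand reference gene.
#'
#' @param locus A `gene_locus`.
#' @param reference Reference [annotation()].
#' @param min_gene_overlap Span-overlap fraction separating novel from known
#'   (default 0.2).
#' @param policy Overlap denominator policy, see [overlap_fraction()].
#' @return List with `id`, `level = "gene"`, `verdict` (`"known"`/`"novel"`),
#'   `reason` (`low_overlap`, `antisense` or `NA`), `matched` (character
#'   vector of reference gene ids; empty iff reason is `low_overlap`).
#' @export
classify_gene_novelty <- function(locus, reference, min_gene_overlap = 0.2,
                                  policy = "shorter") {
  span <- c(locus$start, locus$end)
  cand <- overlapping_loci(reference, locus$chrom, locus$start, locus$end)
  if (length(cand)) {
    idx <- reference$index[match(cand, reference$index$locus), , drop = FALSE]
    frac <- vapply(seq_len(nrow(idx)), function(i)
      overlap_fraction(span, c(idx$start[i], idx$end[i]), policy), 0)
    strong <- frac >= min_gene_overlap
  } else {
    idx <- NULL; frac <- numeric(0); strong <- logical(0)
  }
  if (!any(strong)) {
    return(list(id = locus$id, level = "gene", verdict = "novel",
                reason = "low_overlap", matched = character(0)))
  }
  same <- strong & idx$strand == locus$strand
  if (!any(same)) {
    return(list(id = locus$id, level = "gene", verdict = "novel",
                reason = "antisense", matched = idx$locus[strong]))
  }
  best <- idx$locus[same][which.max(frac[same])]
  list(id = locus$id, level = "gene", verdict = "known", reason = NA_character_,
       matched = best)
}

#' Classify an isoform of a known gene as novel or known
#'
#' An isoform is \strong{novel} when its splice chain contains at least one
#' site absent from the union of the matched reference gene's splice chains,
#' \emph{and} it is not the case that both the isoform and every annotated
#' transcript of the gene are single-exon (the single-exon blocking rule: two
#' mono-exon structures differ only in their termini, which carry no splicing
#' information). An isoform whose chain exactly equals a reference chain is
#' known with reason `exact`; a mono-exon isoform over a mono-exon-only gene
#' is known with reason `single_exon_conflict_pass`.
#'
#' @param t A `transcript_model` assigned to a known gene.
#' @param matched_gene The matched reference `gene_locus`.
#' @return List with `id`, `level = "isoform"`, `verdict`, `reason`,
#'   `new_sites` (numeric vector), `matched` (reference gene id).
#' @export
classify_isoform_novelty <- function(t, matched_gene) {
  ref_chains <- lapply(matched_gene$transcripts, splice_chain)
  ref_sites <- sort(unique(unlist(ref_chains, use.names = FALSE)))
  chain <- splice_chain(t)
  single_exon_t <- n_exons(t) == 1L
  all_ref_single <- all(lengths(ref_chains) == 0L)
  if (single_exon_t && all_ref_single) {
    return(list(id = t$id, level = "isoform", verdict = "known",
                reason = "single_exon_conflict_pass", new_sites = numeric(0),
                matched = matched_gene$id))
  }
  new_sites <- setdiff(chain, ref_sites)
  if (length(new_sites) > 0L) {
    return(list(id = t$id, level = "isoform", verdict = "novel",
                reason = "new_splice_site", new_sites = new_sites,
                matched = matched_gene$id))
  }
  exact <- any(vapply(ref_chains, function(rc)
    length(rc) == length(chain) && all(rc == chain), TRUE))
  list(id = t$id, level = "isoform", verdict = "known",
       reason = if (exact) "exact" else NA_character_,
       new_sites = numeric(0), matched = matched_gene$id)
}

#' Assign each transcript one of seven structural categories
#'
#' Every collapsed transcript receives exactly one label by deterministic
#' priority: `fusion_span` (flagged by the fusion module) >` antisense` >
#' `novel_gene_intergenic` > `full_splice_match` (chain identical to a
#' reference chain of the matched gene) > `incomplete_splice_match` (chain is
#' a contiguous run of a reference chain) > `novel_isoform_known_gene`
#' (multi-exon, neither of the above: new sites or a novel combination) >
#' `single_exon_overlap` (mono-exon transcript over a known gene).
#'
#' @param collapsed Collapsed [annotation()].
#' @param reference Reference [annotation()].
#' @param fusion_ids Character vector of transcript ids flagged as fusions.
#' @inheritParams classify_gene_novelty
#' @return Data frame with columns `transcript_id`, `locus_id`, `category`,
#'   `matched_gene`.
#' @export
assign_structural_category <- function(collapsed, reference,
                                       fusion_ids = character(0),
                                       min_gene_overlap = 0.2,
                                       policy = "shorter") {
  rows <- list()
  for (l in collapsed$loci) {
    gcall <- classify_gene_novelty(l, reference, min_gene_overlap, policy)
    mg <- if (gcall$verdict == "known") reference$loci[[gcall$matched[1L]]]
          else NULL
    for (t in l$transcripts) {
      cat_ <- if (t$id %in% fusion_ids) {
        "fusion_span"
      } else if (gcall$verdict == "novel") {
        if (gcall$reason == "antisense") "antisense" else "novel_gene_intergenic"
      } else {
        chain <- splice_chain(t)
        ref_chains <- lapply(mg$transcripts, splice_chain)
        if (n_exons(t) == 1L) {
          "single_exon_overlap"
        } else if (any(vapply(ref_chains, function(rc)
                   length(rc) == length(chain) && all(rc == chain), TRUE))) {
          "full_splice_match"
        } else if (any(vapply(ref_chains, function(rc)
                   chain_run_index(chain, rc) > 0L, TRUE))) {
          "incomplete_splice_match"
        } else {
          "novel_isoform_known_gene"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = t$id, locus_id = l$id, category = cat_,
        matched_gene = if (is.null(mg)) NA_character_ else mg$id,
        stringsAsFactors = FALSE)
    }
  }
  out <- rbind_rows(rows,
    data.frame(transcript_id = character(0), locus_id = character(0),
               category = character(0), matched_gene = character(0),
               stringsAsFactors = FALSE))
  out[order(out$transcript_id), , drop = FALSE]
}

#' Classify all loci and isoforms of a collapsed annotation
#'
#' Runs [classify_gene_novelty()] on every locus and, for loci matched to a
#' known reference gene, [classify_isoform_novelty()] on every member
#' isoform, then attaches the structural category.
#'
#' @inheritParams assign_structural_category
#' @return Data frame with columns `transcript_id`, `locus_id`,
#'   `gene_verdict`, `gene_reason`, `isoform_verdict`, `isoform_reason`,
#'   `category`, `matched_gene`.
#' @export
classify_novelty <- function(collapsed, reference, fusion_ids = character(0),
                             min_gene_overlap = 0.2, policy = "shorter") {
  cats <- assign_structural_category(collapsed, reference, fusion_ids,
                                     min_gene_overlap, policy)
  rows <- list()
  for (l in collapsed$loci) {
    gcall <- classify_gene_novelty(l, reference, min_gene_overlap, policy)
    mg <- if (gcall$verdict == "known") reference$loci[[gcall$matched[1L]]]
          else NULL
    for (t in l$transcripts) {
      icall <- if (!is.null(mg)) classify_isoform_novelty(t, mg) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = t$id, locus_id = l$id,
        gene_verdict = gcall$verdict, gene_reason = gcall$reason,
        isoform_verdict = if (is.null(icall)) NA_character_ else icall$verdict,
        isoform_reason = if (is.null(icall)) NA_character_ else icall$reason,
        matched_gene = if (is.null(mg)) NA_character_ else mg$id,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(0), locus_id = character(0),
                      gene_verdict = character(0), gene_reason = character(0),
                      isoform_verdict = character(0),
                      isoform_reason = character(0),
                      matched_gene = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- merge(out, cats[, c("transcript_id", "category")],
               by = "transcript_id", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Summarize novelty calls
#'
#' Counts per gene verdict/reason, isoform verdict and structural category,
#' split into single- and multi-exon transcripts.
#'
#' @param calls Data frame from [classify_novelty()].
#' @param collapsed The collapsed [annotation()] the calls refer to.
#' @return Data frame with columns `class`, `value`, `n_single_exon`,
#'   `n_multi_exon`, `n`; counts within each `class` sum to the number of
#'   transcripts.
#' @export
novelty_summary <- function(calls, collapsed) {
  txs <- annotation_transcripts(collapsed)
  multi <- vapply(txs, n_exons, 0L)[calls$transcript_id] > 1L
  tab <- function(cls, val) {
    val <- ifelse(is.na(val), "none", val)
    out <- do.call(rbind, lapply(sort(unique(val)), function(v)
      data.frame(class = cls, value = v,
                 n_single_exon = sum(val == v & !multi),
                 n_multi_exon = sum(val == v & multi),
                 n = sum(val == v), stringsAsFactors = FALSE)))
    out
  }
  if (nrow(calls) == 0L)
    return(data.frame(class = character(0), value = character(0),
                      n_single_exon = integer(0), n_multi_exon = integer(0),
                      n = integer(0), stringsAsFactors = FALSE))
  rbind(tab("gene_verdict", calls$gene_verdict),
        tab("gene_reason", calls$gene_reason),
        tab("isoform_verdict", calls$isoform_verdict),
        tab("category", calls$category))
}
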