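#' Detect fusion transcripts from multi-segment alignments
#'
#' A transcript whose aligned segments occupy more than one gene locus is a
#' fusion candidate. Each segment is assigned to the annotation locus it
#' satisfies the [same_locus()] test against (same chromosome/strand, span
#' and exon overlap); segments on unannotated regions receive a provisional
#' locus id and still count. A call is emitted when the segments map to at
#' least two distinct loci; it is `inter_chromosome` when the segments lie on
#' different chromosomes, otherwise `intra_chromosome` (which, by
#' construction, requires two genuinely distinct loci rather than far-apart
#' exons of one locus).
#'
#' @param segments List of fusion candidates; each element is a list with
#'   `id`, `flnc_support`, and `segments` (a list of `transcript_model`
#'   parts, at least 2).
#' @param ann An [annotation()] (typically the collapsed one) providing loci.
#' @param min_segment_span Minimum genomic span (bp) for a segment to count a
#'   locus hit (noise guard, default 50).
#' @inheritParams same_locus
#' @return Data frame with one row per call: `transcript_id`, `n_segments`,
#'   `n_loci`, `loci` (comma-separated), `category`, `flnc_support`,
#'   `well_supported`.
#' @export
detect_fusions <- function(segments, ann, min_segment_span = 50,
                           min_span_overlap = 0.2, min_exon_overlap = 0.2,
                           policy = "shorter") {
  rows <- list()
  prov <- 0L
  for (f in segments) {
    stopifnot(length(f$segments) >= 2L)
    segs <- Filter(function(s) tx_span_length(s) >= min_segment_span,
                   f$segments)
    if (length(segs) < 2L) next
    hit <- character(length(segs))
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      lid <- NA_character_
      for (cand in overlapping_loci(ann, s$chrom, tx_start(s), tx_end(s))) {
        l <- ann$loci[[cand]]
        ok <- any(vapply(l$transcripts, function(t)
          same_locus(s, t, min_span_overlap, min_exon_overlap, policy), TRUE))
        if (ok) { lid <- cand; break }
      }
      if (is.na(lid)) {  # unannotated region: provisional locus, still counts
        prov <- prov + 1L
        lid <- sprintf("PROV%04d", prov)
      }
      hit[i] <- lid
    }
    loci <- unique(hit)
    if (length(loci) < 2L) next
    chroms <- unique(vapply(segs, `[[`, "", "chrom"))
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = f$id, n_segments = length(segs), n_loci = length(loci),
      loci = paste(sort(loci), collapse = ","),
      category = if (length(chroms) > 1L) "inter_chromosome"
                 else "intra_chromosome",
      flnc_support = as.integer(f$flnc_support),
      well_supported = as.integer(f$flnc_support) >= 2L,
      stringsAsFactors = FALSE)
  }
  out <- rbind_rows(rows,
    data.frame(transcript_id = character(0), n_segments = integer(0),
               n_loci = integer(0), loci = character(0),
               category = character(0), flnc_support = integer(0),
               well_supported = logical(0), stringsAsFactors = FALSE))
  out[order(out$transcript_id), , drop = FALSE]
}

#' Partition fusion calls by FLNC support
#'
#' Fusion transcripts supported by at least `min_flnc` FLNC reads are the
#' well-supported set; the rest are singly supported. Counts are conserved.
#'
#' @param calls Data frame from [detect_fusions()].
#' @param min_flnc Support threshold (default 2).
#' @return List with `well_supported` and `singly_supported` data frames.
#' @export
support_filter <- function(calls, min_flnc = 2) {
  ok <- calls$flnc_support >= min_flnc
  list(well_supported = calls[ok, , drop = FALSE],
       singly_supported = calls[!ok, , drop = FALSE])
}
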