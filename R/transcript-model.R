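#' Construct a transcript model
#'
#' A transcript model is the atom of the whole pipeline: an exon-block
#' structure on a genome, together with the alignment percent identity (PID)
#' of the full-length read(s) it summarises, the number of FLNC reads
#' supporting it, and per-intron flags recording whether each splice junction
#' is annotated or supported by short-read (NGS) data.
#'
#' Coordinates are 0-based half-open throughout the package; GFF3/GTF I/O
#' performs the conversion to and from the 1-based closed convention.
#'
#' @param id Unique transcript identifier.
#' @param chrom Chromosome name.
#' @param strand One of `"+"`, `"-"` or `"*"` (unknown).
#' @param exons Two-column numeric matrix (`start`, `end`), 0-based half-open,
#'   sorted by start and pairwise disjoint with gaps of at least 1 bp.
#' @param pid Alignment percent identity in `[0, 100]`.
#' @param flnc_support Non-negative integer count of supporting FLNC reads.
#' @param source_sample Optional sample label (e.g. `"s17033-T"`).
#' @param ngs_support Logical vector, one flag per intron, `TRUE` when the
#'   junction is NGS-annotated or NGS-supported. Recycled from a scalar.
#' @return An object of class `transcript_model`.
#' @examples
#' t1 <- transcript_model("tx1", "chr1", "+", cbind(c(0, 200), c(100, 300)))
#' splice_chain(t1)
#' @export
transcript_model <- function(id, chrom, strand, exons, pid = 100,
                             flnc_support = 1L, source_sample = NA_character_,
                             ngs_support = TRUE) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  n_introns <- max(0L, nrow(exons) - 1L)
  ngs_support <- rep_len(as.logical(ngs_support), n_introns)
  obj <- structure(list(id = as.character(id), chrom = as.character(chrom),
                        strand = strand, exons = exons, pid = as.numeric(pid),
                        flnc_support = as.integer(flnc_support),
                        source_sample = source_sample,
                        ngs_support = ngs_support),
                   class = "transcript_model")
  validate_transcript_model(obj)
}

validate_transcript_model <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  if (!nzchar(t$chrom)) stop("transcript ", t$id, ": empty chromosome")
  if (!t$strand %in% c("+", "-", "*"))
    stop("transcript ", t$id, ": invalid strand '", t$strand, "'")
  ex <- t$exons
  if (nrow(ex) == 0L) stop("transcript ", t$id, ": no exons")
  if (any(ex[, "end"] <= ex[, "start"]))
    stop("transcript ", t$id, ": exon with end <= start")
  if (is.unsorted(ex[, "start"], strictly = TRUE) && nrow(ex) > 1L)
    stop("transcript ", t$id, ": exons not sorted by start")
  if (nrow(ex) > 1L && any(ex[-nrow(ex), "end"] >= ex[-1L, "start"]))
    stop("transcript ", t$id, ": exons overlap or touch (introns need >= 1 bp)")
  if (is.na(t$pid) || t$pid < 0 || t$pid > 100)
    stop("transcript ", t$id, ": pid outside [0, 100]")
  if (t$flnc_support < 0L)
    stop("transcript ", t$id, ": negative flnc_support")
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s  %s:%s-%s(%s)  %d exon(s)  pid=%.4g  flnc=%d\n",
              x$id, x$chrom, format(tx_start(x), scientific = FALSE),
              format(tx_end(x), scientific = FALSE), x$strand,
              nrow(x$exons), x$pid, x$flnc_support))
  invisible(x)
}

n_exons <- function(t) nrow(t$exons)
tx_start <- function(t) t$exons[1L, "start"]
tx_end <- function(t) t$exons[nrow(t$exons), "end"]
tx_span <- function(t) c(start = tx_start(t), end = tx_end(t))
tx_span_length <- function(t) tx_end(t) - tx_start(t)
exon_length_sum <- function(t) sum(t$exons[, "end"] - t$exons[, "start"])

#' Intron intervals of a transcript model
#'
#' @param t A `transcript_model`.
#' @return Two-column matrix of intron (`start`, `end`) intervals, 0-based
#'   half-open; zero rows for single-exon transcripts.
#' @export
introns <- function(t) {
  k <- nrow(t$exons)
  if (k < 2L)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = t$exons[-k, "end"], end = t$exons[-1L, "start"])
}

#' Splice chain (internal splice-site structure) of a transcript
#'
#' The splice chain is the ordered set of all internal exon boundaries of a
#' transcript -- each exon end followed by the next exon start -- excluding
#' the transcript's own start and end. It is the "sequence structure" used to
#' decide isoform identity: two multi-exon transcripts are the same isoform
#' exactly when their splice chains are identical, regardless of how far their
#' terminal exons extend.
#'
#' @param t A `transcript_model`.
#' @return Numeric vector of length `2 * (n_exons - 1)`; empty for
#'   single-exon transcripts.
#' @examples
#' t1 <- transcript_model("tx", "chr1", "+",
#'                        cbind(c(0, 200, 400), c(100, 300, 500)))
#' splice_chain(t1)  # 100 200 300 400
#' @export
splice_chain <- function(t) {
  k <- nrow(t$exons)
  if (k < 2L) return(numeric(0))
  as.numeric(rbind(t$exons[-k, "end"], t$exons[-1L, "start"]))
}

#' Overlap fraction between two genomic intervals
#'
#' Overlap length divided by the length of one of the intervals, the
#' denominator chosen by `policy`. The locus-merging rule ("20% overlap for
#' two sequences, at least one exon overlapping to more than 20%") never
#' states which length the fraction refers to; the default, the shorter
#' interval, is the most permissive reading and merges aligned fragments into
#' their parent loci. Intervals are half-open, so intervals that merely touch
#' do not overlap.
#'
#' @param a,b Numeric length-2 vectors `c(start, end)`, 0-based half-open,
#'   assumed on the same chromosome.
#' @param policy Denominator: `"shorter"` (default; equivalently, the overlap
#'   passes a threshold if either fraction does) or `"reciprocal"` (the longer
#'   interval; both fractions must pass).
#' @return Fraction in `[0, 1]`; 0 when disjoint.
#' @examples
#' overlap_fraction(c(100, 500), c(400, 900))  # 100/400 = 0.25
#' @export
overlap_fraction <- function(a, b, policy = c("shorter", "reciprocal")) {
  policy <- match.arg(policy)
  ov <- min(a[2L], b[2L]) - max(a[1L], b[1L])
  if (ov <= 0) return(0)
  la <- a[2L] - a[1L]
  lb <- b[2L] - b[1L]
  denom <- if (policy == "shorter") min(la, lb) else max(la, lb)
  ov / denom
}

# overlap length (bp) of two half-open intervals; 0 when disjoint
interval_overlap <- function(a, b) max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))

#' Construct a gene locus
#'
#' A locus groups transcript models on one chromosome and strand; its span is
#' the hull of all member exons.
#'
#' @param id Locus identifier.
#' @param transcripts List of `transcript_model`, all on one chromosome and
#'   strand.
#' @return An object of class `gene_locus`.
#' @export
gene_locus <- function(id, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chroms) != 1L)
    stop("locus ", id, ": members on multiple chromosomes")
  if (length(strands) != 1L)
    stop("locus ", id, ": members on multiple strands")
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  structure(list(id = as.character(id), chrom = chroms, strand = strands,
                 start = min(vapply(transcripts, tx_start, 0)),
                 end = max(vapply(transcripts, tx_end, 0)),
                 transcripts = transcripts),
            class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s  %s:%s-%s(%s)  %d transcript(s)\n",
              x$id, x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), x$strand,
              length(x$transcripts)))
  invisible(x)
}

#' Construct an annotation (indexed collection of gene loci)
#'
#' Both the reference annotation and the collapsed pipeline output take this
#' form. Transcript identifiers must be unique across loci; an interval index
#' over locus spans supports overlap queries.
#'
#' @param loci List of `gene_locus` objects.
#' @return An object of class `annotation`.
#' @export
annotation <- function(loci = list()) {
  names(loci) <- vapply(loci, `[[`, "", "id")
  tx_ids <- unlist(lapply(loci, function(l) names(l$transcripts)),
                   use.names = FALSE)
  if (anyDuplicated(tx_ids))
    stop("duplicate transcript ids: ",
         paste(unique(tx_ids[duplicated(tx_ids)]), collapse = ", "))
  idx <- if (length(loci)) {
    data.frame(locus = names(loci),
               chrom = vapply(loci, `[[`, "", "chrom"),
               start = vapply(loci, `[[`, 0, "start"),
               end = vapply(loci, `[[`, 0, "end"),
               strand = vapply(loci, `[[`, "", "strand"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(locus = character(0), chrom = character(0), start = numeric(0),
               end = numeric(0), strand = character(0))
  }
  structure(list(loci = loci, index = idx), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %d loci, %d transcripts on %d sequence(s)\n",
              n_loci(x), n_transcripts(x), length(unique(x$index$chrom))))
  invisible(x)
}

#' @rdname annotation
#' @param ann An `annotation`.
#' @export
n_loci <- function(ann) length(ann$loci)

#' @rdname annotation
#' @export
n_transcripts <- function(ann) {
  sum(vapply(ann$loci, function(l) length(l$transcripts), 0L))
}

#' Flatten an annotation into a list of transcript models
#'
#' @param ann An `annotation`.
#' @return Named list of `transcript_model` (names are transcript ids).
#' @export
annotation_transcripts <- function(ann) {
  out <- unlist(lapply(ann$loci, `[[`, "transcripts"), recursive = FALSE,
                use.names = FALSE)
  if (is.null(out)) out <- list()
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

# map transcript id -> locus id
locus_of_transcript <- function(ann) {
  ids <- lapply(ann$loci, function(l) names(l$transcripts))
  stats::setNames(rep(names(ids), lengths(ids)), unlist(ids, use.names = FALSE))
}

# locus ids whose span overlaps [start, end) on chrom (any strand)
overlapping_loci <- function(ann, chrom, start, end) {
  idx <- ann$index
  hit <- idx$chrom == chrom & idx$start < end & idx$end > start
  idx$locus[hit]
}
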