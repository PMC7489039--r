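#' Read a gene annotation from GFF3 or GTF
#'
#' Exon features are grouped into transcript models and transcripts into gene
#' loci. Coordinates are converted from the 1-based closed GFF3/GTF convention
#' to the package's 0-based half-open intervals. Transcript and gene
#' identifiers are taken from `transcript_id`/`gene_id` attributes when
#' present (always the case for GTF) and otherwise from `Parent`/`ID`
#' relations (GFF3). Optional `pid`, `flnc_support`, `source_sample` and
#' `ngs_support` attributes on mRNA/transcript features are restored, so FLNC
#' transcript sets written by [write_annotation()] round-trip.
#'
#' Features with strand `"."` are accepted and kept with strand `"*"`;
#' strand-sensitive operations exclude them with a warning.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"gtf"`.
#' @return An [annotation()] object.
#' @export
read_annotation <- function(path, format = c("gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1000L, warn = FALSE)) == 0L ||
      !any(!grepl("^#|^\\s*$", readLines(path, warn = FALSE))))
    return(annotation())
  gr <- rtracklayer::import(path, format = format)
  gr_to_annotation(gr)
}

# Build an annotation from an imported GRanges of gene/mRNA/exon features.
gr_to_annotation <- function(gr) {
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  if (!any(is_exon)) return(annotation())

  first_chr <- function(x) if (length(x)) as.character(x)[1L] else NA_character_
  # transcript-level metadata (GFF3 mRNA rows), if any
  tx_meta <- NULL
  if (any(is_tx)) {
    ids <- as.character(md$ID[is_tx])
    if (!is.null(md$transcript_id))
      ids <- ifelse(is.na(ids), as.character(md$transcript_id[is_tx]), ids)
    tx_meta <- data.frame(id = ids, stringsAsFactors = FALSE)
    tx_meta$gene <- if (!is.null(md$Parent))
      vapply(md$Parent[is_tx], first_chr, "") else NA_character_
    if (!is.null(md$gene_id))
      tx_meta$gene <- ifelse(is.na(tx_meta$gene),
                             as.character(md$gene_id[is_tx]), tx_meta$gene)
    for (f in c("pid", "flnc_support", "source_sample", "ngs_support")) {
      tx_meta[[f]] <- if (!is.null(md[[f]]))
        as.character(md[[f]][is_tx]) else NA_character_
    }
  }

  ex <- gr[is_exon]
  exd <- S4Vectors::mcols(ex)
  tx_id <- if (!is.null(exd$transcript_id) && !all(is.na(exd$transcript_id))) {
    as.character(exd$transcript_id)
  } else if (!is.null(exd$Parent)) {
    vapply(exd$Parent, first_chr, "")
  } else stop("exon features carry neither transcript_id nor Parent")
  if (anyNA(tx_id) || !all(nzchar(tx_id)))
    stop("exon feature without a transcript identifier")
  gene_id <- if (!is.null(exd$gene_id) && !all(is.na(exd$gene_id)))
    as.character(exd$gene_id) else rep(NA_character_, length(ex))

  ord <- order(tx_id, GenomicRanges::start(ex))
  ex <- ex[ord]; tx_id <- tx_id[ord]; gene_id <- gene_id[ord]
  starts <- GenomicRanges::start(ex) - 1  # to 0-based half-open
  ends <- as.numeric(GenomicRanges::end(ex))
  chroms <- as.character(GenomicRanges::seqnames(ex))
  strands <- as.character(GenomicRanges::strand(ex))

  by_tx <- split(seq_along(tx_id), tx_id)
  tx_gene <- vapply(by_tx, function(i) gene_id[i[1L]], "")
  if (!is.null(tx_meta)) {
    m <- match(names(by_tx), tx_meta$id)
    tx_gene <- ifelse(is.na(tx_gene) & !is.na(m), tx_meta$gene[m], tx_gene)
  }
  transcripts <- lapply(names(by_tx), function(tid) {
    i <- by_tx[[tid]]
    pid <- 100; flnc <- 1L; src <- NA_character_; ngs <- TRUE
    if (!is.null(tx_meta)) {
      m <- match(tid, tx_meta$id)
      if (!is.na(m)) {
        if (!is.na(tx_meta$pid[m])) pid <- as.numeric(tx_meta$pid[m])
        if (!is.na(tx_meta$flnc_support[m]))
          flnc <- as.integer(tx_meta$flnc_support[m])
        src <- tx_meta$source_sample[m]
        if (!is.na(tx_meta$ngs_support[m]))
          ngs <- strsplit(tx_meta$ngs_support[m], ",", fixed = TRUE)[[1]] == "1"
      }
    }
    transcript_model(tid, chroms[i[1L]],
                     if (strands[i[1L]] %in% c("+", "-")) strands[i[1L]] else "*",
                     cbind(starts[i], ends[i]), pid = pid, flnc_support = flnc,
                     source_sample = src, ngs_support = ngs)
  })
  names(transcripts) <- names(by_tx)

  # group transcripts into loci by gene id; orphan transcripts get their own
  gkey <- ifelse(is.na(tx_gene) | !nzchar(tx_gene),
                 paste0("locus_of_", names(by_tx)), tx_gene)
  grp <- split(transcripts, gkey)
  loci <- Map(function(txs, gid) gene_locus(gid, txs),
              grp, sub("^locus_of_", "", names(grp)))
  annotation(unname(loci))
}

#' Write an annotation to GFF3
#'
#' Emits gene, mRNA and exon features with `ID`/`Parent` relations plus
#' `gene_id`/`transcript_id` attributes. Internal 0-based half-open
#' coordinates are converted back to 1-based closed. Transcript `pid`,
#' `flnc_support`, `source_sample` and per-intron `ngs_support` flags are
#' written as mRNA attributes, making `read_annotation(write_annotation(A))`
#' the identity on ids, coordinates, strands and metadata. Unknown strand is
#' written as `"."`.
#'
#' @param ann An [annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  rows <- list()
  for (l in ann$loci) {
    st <- if (l$strand %in% c("+", "-")) l$strand else "*"
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = l$chrom, start = l$start + 1, end = l$end, strand = st,
      type = "gene", ID = l$id, Parent = NA, gene_id = l$id,
      transcript_id = NA, pid = NA, flnc_support = NA, source_sample = NA,
      ngs_support = NA, stringsAsFactors = FALSE)
    for (t in l$transcripts) {
      ngs <- if (length(t$ngs_support))
        paste(as.integer(t$ngs_support), collapse = ",") else NA
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = t$chrom, start = tx_start(t) + 1, end = tx_end(t), strand = st,
        type = "mRNA", ID = t$id, Parent = l$id, gene_id = l$id,
        transcript_id = t$id, pid = t$pid, flnc_support = t$flnc_support,
        source_sample = t$source_sample, ngs_support = ngs,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = t$chrom, start = t$exons[, "start"] + 1, end = t$exons[, "end"],
        strand = st, type = "exon", ID = NA, Parent = t$id, gene_id = l$id,
        transcript_id = t$id, pid = NA, flnc_support = NA, source_sample = NA,
        ngs_support = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = df$type, ID = df$ID, Parent = df$Parent, gene_id = df$gene_id,
    transcript_id = df$transcript_id, pid = df$pid,
    flnc_support = df$flnc_support, source_sample = df$source_sample,
    ngs_support = df$ngs_support)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript models from a BED12 file
#'
#' Alternate input for aligned transcript models: each BED12 record's blocks
#' become the exons of one `transcript_model`. The score column, when
#' integral and positive, is used as the FLNC support count.
#'
#' @param path Path to a BED12 file.
#' @return List of `transcript_model`.
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    off <- GenomicRanges::start(gr)[i] - 1  # 0-based feature start
    bl <- if (!is.null(md$blocks)) md$blocks[[i]] else
      IRanges::IRanges(1, GenomicRanges::width(gr)[i])
    exons <- cbind(off + IRanges::start(bl) - 1, off + IRanges::end(bl))
    sc <- if (!is.null(md$score) && !is.na(md$score[i]) && md$score[i] > 0)
      as.integer(md$score[i]) else 1L
    st <- as.character(GenomicRanges::strand(gr))[i]
    out[[i]] <- transcript_model(
      if (!is.null(md$name)) as.character(md$name[i]) else paste0("bed_", i),
      as.character(GenomicRanges::seqnames(gr))[i],
      if (st %in% c("+", "-")) st else "*",
      exons, flnc_support = sc)
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}
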