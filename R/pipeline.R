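#' Run the full synthetic-data pipeline
#'
#' Orchestrates simulate -> collapse -> classify -> splice -> fuse ->
#' express: generates a reference annotation, an FLNC set and a count matrix
#' from `config`, collapses the FLNC transcripts into loci/isoforms,
#' classifies novelty and structural categories, enumerates AS events per
#' sample-free locus, detects fusions, and calls DEGs for the
#' treatment-vs-control contrast. Identical `config` (same seed) gives
#' identical outputs; when `out_dir` is given, all stage outputs are written
#' there (GFF3 annotations, TSV tables).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List with `reference`, `flnc`, `collapsed`, `report`, `novelty`,
#'   `events`, `fusions`, `counts`, `degs`, `summary` and `truth` components.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL) {
  ref <- simulate_reference(config)
  flnc <- simulate_flnc(ref, config)
  col <- collapse_transcripts(flnc$transcripts)
  fus <- detect_fusions(flnc$fusions, col$annotation)
  nov <- classify_novelty(col$annotation, ref$annotation,
                          fusion_ids = fus$transcript_id)
  events <- enumerate_annotation_events(col$annotation)
  cnt <- simulate_counts(ref$annotation, config)
  groups <- split(cnt$em$design$sample, cnt$em$design$treatment)
  stats <- deg_test(cnt$em, groups[[config$treatments[1L]]],
                    groups[[config$treatments[2L]]])
  degs <- call_degs(stats)

  smry <- data.frame(
    stage = c("loci", "isoforms", "novel_gene_loci", "novel_isoforms",
              "as_events", "fusion_calls", "degs"),
    n = c(n_loci(col$annotation), n_transcripts(col$annotation),
          length(unique(nov$locus_id[nov$gene_verdict == "novel"])),
          sum(nov$isoform_verdict == "novel", na.rm = TRUE),
          if (is.null(events)) 0L else nrow(events),
          nrow(fus), sum(degs$call != "not_de")),
    stringsAsFactors = FALSE)

  out <- list(reference = ref$annotation, flnc = flnc$transcripts,
              collapsed = col$annotation, report = col$report,
              novelty = nov, events = events, fusions = fus,
              counts = cnt$em, degs = degs, summary = smry,
              truth = list(reference = ref$truth, flnc = flnc$truth,
                           counts = cnt$truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_annotation(ref$annotation, file.path(out_dir, "reference.gff3"))
    write_annotation(col$annotation, file.path(out_dir, "collapsed.gff3"))
    wtsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(col$report, "collapse_report.tsv")
    wtsv(nov, "novelty.tsv")
    if (!is.null(events)) wtsv(events, "as_events.tsv")
    wtsv(fus, "fusions.tsv")
    wtsv(cbind(gene = rownames(cnt$em$counts), as.data.frame(cnt$em$counts)),
         "counts.tsv")
    wtsv(degs, "degs.tsv")
    wtsv(smry, "summary.tsv")
    wtsv(flnc$truth, "truth_flnc.tsv")
    wtsv(cnt$truth, "truth_counts.tsv")
  }
  out
}

#' Precision/recall of a predicted id set against a truth set
#'
#' @param predicted,truth Character vectors of ids.
#' @return List with `precision`, `recall`, `f1` (NA when undefined) and
#'   `exact` (`TRUE` when precision and recall are both 1).
#' @export
compare_sets <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  precision <- if (length(predicted)) tp / length(predicted) else NA_real_
  recall <- if (length(truth)) tp / length(truth) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       exact = isTRUE(precision == 1) && isTRUE(recall == 1))
}

#' Compare pipeline outputs against the planted truth
#'
#' Builds a per-class precision/recall table for the removal-reason labels,
#' the novelty calls, the fusion categories and the DEG calls of a
#' [run_pipeline()] result.
#'
#' @param run Result of [run_pipeline()].
#' @return Data frame with columns `class`, `n_truth`, `n_predicted`,
#'   `precision`, `recall`, `f1`.
#' @export
compare_to_truth <- function(run) {
  ft <- run$truth$flnc
  rep_ <- run$report
  rows <- list()
  add <- function(class, predicted, truth) {
    cs <- compare_sets(predicted, truth)
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class, n_truth = length(unique(truth)),
      n_predicted = length(unique(predicted)),
      precision = cs$precision, recall = cs$recall, f1 = cs$f1,
      stringsAsFactors = FALSE)
  }
  for (reason in c("degraded_5p", "structure_subset", "low_pid_unsupported",
                   "duplicate_shorter")) {
    add(paste0("removed_", reason),
        rep_$transcript_id[rep_$status == "removed" &
                           !is.na(rep_$reason) & rep_$reason == reason],
        ft$id[ft$expected == reason])
  }
  add("kept", rep_$transcript_id[rep_$status == "kept"],
      ft$id[ft$expected == "kept"])

  nov <- run$novelty
  novel_gene_pred <- nov$transcript_id[nov$gene_verdict == "novel"]
  add("novel_gene_transcripts", novel_gene_pred,
      ft$id[ft$label %in% c("novel_gene", "antisense")])
  add("novel_isoforms",
      nov$transcript_id[!is.na(nov$isoform_verdict) &
                        nov$isoform_verdict == "novel"],
      ft$id[ft$label == "novel_isoform"])

  fus_truth <- ft[ft$label == "fusion", , drop = FALSE]
  add("fusion", run$fusions$transcript_id, fus_truth$id)
  for (catg in c("inter_chromosome", "intra_chromosome")) {
    add(paste0("fusion_", catg),
        run$fusions$transcript_id[run$fusions$category == catg],
        fus_truth$id[fus_truth$category == catg])
  }

  ct <- run$truth$counts
  add("deg", run$degs$gene[run$degs$call != "not_de"], ct$gene[ct$is_de])
  do.call(rbind, c(rows, make.row.names = FALSE))
}
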