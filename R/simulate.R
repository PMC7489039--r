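#' Configuration for the synthetic transcriptome generator
#'
#' The generator emulates the data regimes the pipeline consumes: a
#' multi-exon reference annotation with alternatively spliced isoforms; an
#' FLNC transcript set containing exact copies plus planted corruptions
#' (5'-degraded copies, structure subsets, low-PID singletons, shorter
#' duplicates, novel isoforms, intergenic and antisense novel genes, fusion
#' transcripts); and negative-binomial count matrices over a
#' 2-variety x 2-treatment x 3-replicate design with planted log2 fold
#' changes. All randomness flows from `seed`; a fixed seed gives
#' byte-identical outputs.
#'
#' @param seed Integer seed.
#' @param n_genes Number of reference genes.
#' @param n_chroms Number of chromosomes (genes distributed round-robin).
#' @param exon_mean Mean of the geometric exon-count distribution
#'   (`n_exons = 1 + Geom`), capped at 12.
#' @param exon_length_range,intron_length_range,intergenic_gap_range Integer
#'   ranges (bp) for exon lengths, intron lengths and gaps between genes.
#' @param isoforms_per_gene Length-2 integer vector: min/max isoforms per
#'   gene; extra isoforms are built by applying one splicing operator each.
#' @param as_probs Named probabilities for the splicing operators
#'   `retain_intron`, `skip_exon`, `alt_acceptor`, `alt_donor`,
#'   `alt_exon_end` (normalised internally).
#' @param degraded_rate,subset_rate,low_pid_rate,duplicate_rate,
#'   novel_isoform_rate,novel_gene_rate,antisense_rate,fusion_rate Corruption
#'   rates, each the expected number of planted transcripts of that class per
#'   reference gene. At most one corruption is planted per gene so every
#'   transcript has exactly one primary truth label.
#' @param low_pid_range PID range for low-PID singletons (below the
#'   99-percent threshold); clean copies draw PID from `[99, 100]`.
#' @param flnc_lambda Poisson rate for extra FLNC support of clean copies.
#' @param nb_mean_range Range of gene base means (counts).
#' @param nb_dispersion Negative-binomial dispersion (0 gives Poisson).
#' @param de_fraction Fraction of genes with a planted treatment effect.
#' @param de_log2fc_range Magnitude range of planted log2 fold changes.
#' @param varieties,treatments,n_reps Sample design; labels follow the
#'   `<variety>-<treatment><replicate>` scheme (e.g. `s17235-T1`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, n_chroms = 3L,
                       exon_mean = 5, exon_length_range = c(100L, 300L),
                       intron_length_range = c(80L, 400L),
                       intergenic_gap_range = c(2000L, 8000L),
                       isoforms_per_gene = c(1L, 3L),
                       as_probs = c(retain_intron = 0.3, skip_exon = 0.3,
                                    alt_acceptor = 0.15, alt_donor = 0.15,
                                    alt_exon_end = 0.1),
                       degraded_rate = 0.10, subset_rate = 0.10,
                       low_pid_rate = 0.05, duplicate_rate = 0.10,
                       novel_isoform_rate = 0.05, novel_gene_rate = 0.05,
                       antisense_rate = 0.03, fusion_rate = 0.03,
                       low_pid_range = c(90, 98.5), flnc_lambda = 1,
                       nb_mean_range = c(20, 500), nb_dispersion = 0.05,
                       de_fraction = 0.1, de_log2fc_range = c(2, 4),
                       varieties = c("s17033", "s17235"),
                       treatments = c("T", "CK"), n_reps = 3L) {
  if (exon_length_range[1L] < 30L || intron_length_range[1L] < 10L)
    stop("infeasible length ranges: exons need >= 30 bp, introns >= 10 bp")
  if (any(as_probs < 0) || sum(as_probs) <= 0)
    stop("invalid splicing-operator probabilities")
  cfg <- as.list(environment())
  cfg$as_probs <- as_probs / sum(as_probs)
  structure(cfg, class = "sim_config")
}

rint <- function(n, range) sample(seq(range[1L], range[2L]), n, replace = TRUE)

# apply one splicing operator to an exon matrix; returns NULL when infeasible,
# else list(exons, event = list(mode, major_type, coords, swap_in)) where
# swap_in = TRUE when the NEW isoform is the event's isoform_in
apply_as_operator <- function(E, strand, op, used_sites) {
  k <- nrow(E)
  if (op == "retain_intron") {
    if (k < 2L) return(NULL)
    j <- sample(k - 1L, 1L)
    coords <- coord_key(cbind(E[j, 2L], E[j + 1L, 1L]))
    E2 <- rbind(E[seq_len(j - 1L), , drop = FALSE],
                c(E[j, 1L], E[j + 1L, 2L]),
                E[-seq_len(j + 1L), , drop = FALSE])
    return(list(exons = E2, event = list(mode = "IR", major_type = "IR",
                                         coords = coords, swap_in = TRUE)))
  }
  if (op == "skip_exon") {
    if (k < 3L) return(NULL)
    j <- if (k == 3L) 2L else sample(2:(k - 1L), 1L)
    coords <- coord_key(E[j, , drop = FALSE])
    return(list(exons = E[-j, , drop = FALSE],
                event = list(mode = "SKIP", major_type = "ES",
                             coords = coords, swap_in = FALSE)))
  }
  if (op %in% c("alt_acceptor", "alt_donor")) {
    if (k < 2L) return(NULL)
    # acceptor = intron 3' end in transcript orientation; on '+' that is the
    # genomic-right boundary (next exon start), on '-' the genomic-left one
    move_right <- (op == "alt_acceptor") == (strand == "+")
    for (j in sample(k - 1L)) {
      l <- E[j, 2L]; r <- E[j + 1L, 1L]
      if (move_right) {
        lo <- max(l + 10, r - 60); hi <- min(E[j + 1L, 2L] - 20, r + 60)
      } else {
        lo <- max(E[j, 1L] + 20, l - 60); hi <- min(r - 10, l + 60)
      }
      if (lo > hi) next
      cand <- setdiff(seq(lo, hi), c(used_sites, if (move_right) r else l))
      if (!length(cand)) next
      new_site <- if (length(cand) == 1L) cand else sample(cand, 1L)
      E2 <- E
      old <- if (move_right) r else l
      if (move_right) E2[j + 1L, 1L] <- new_site else E2[j, 2L] <- new_site
      return(list(exons = E2,
                  event = list(mode = "AE",
                               major_type = if (op == "alt_acceptor") "AA"
                                            else "AD",
                               coords = coord_key(cbind(min(old, new_site),
                                                        max(old, new_site))),
                               swap_in = TRUE)))
    }
    return(NULL)
  }
  if (op == "alt_exon_end") {
    at_start <- sample(c(TRUE, FALSE), 1L)
    if (at_start) {
      w <- E[1L, 2L] - E[1L, 1L]
      if (w < 40) return(NULL)
      d <- sample(10:min(80, w - 20), 1L)
      old <- E[1L, 1L]; E2 <- E; E2[1L, 1L] <- old + d
      new <- old + d
    } else {
      w <- E[k, 2L] - E[k, 1L]
      if (w < 40) return(NULL)
      d <- sample(10:min(80, w - 20), 1L)
      old <- E[k, 2L]; E2 <- E; E2[k, 2L] <- old - d
      new <- old - d
    }
    return(list(exons = E2,
                event = list(mode = "AE", major_type = "other",
                             coords = coord_key(cbind(min(old, new),
                                                      max(old, new))),
                             swap_in = TRUE)))
  }
  stop("unknown operator: ", op)
}

#' Generate a synthetic reference annotation with planted AS isoforms
#'
#' Genes are laid out chromosome by chromosome with intergenic gaps; each
#' gene gets a primary transcript and, per the isoform range, extra isoforms
#' built by single splicing operators whose events are recorded as ground
#' truth in the same `(gene, mode, coords)` key scheme used by
#' [enumerate_as_events()].
#'
#' @param config A [sim_config()].
#' @return List with `annotation` (the reference), and `truth` containing
#'   `genes` (data frame), `isoforms` (id, gene, operator) and `events`
#'   (planted AS events).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  loci <- list()
  gene_rows <- list()
  iso_rows <- list()
  event_rows <- list()
  cursor <- stats::setNames(rep(0, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
  if (config$n_genes == 0L)
    return(list(annotation = annotation(),
                truth = list(genes = data.frame(), isoforms = data.frame(),
                             events = data.frame())))
  for (i in seq_len(config$n_genes)) {
    chrom <- names(cursor)[((i - 1L) %% config$n_chroms) + 1L]
    gid <- sprintf("G%04d", i)
    strand <- sample(c("+", "-"), 1L)
    k <- min(12L, 1L + stats::rgeom(1L, 1 / config$exon_mean))
    exon_w <- rint(k, config$exon_length_range)
    intron_w <- if (k > 1L) rint(k - 1L, config$intron_length_range) else integer(0)
    start <- cursor[chrom] + rint(1L, config$intergenic_gap_range)
    starts <- start + c(0, cumsum(exon_w[-k] + intron_w))
    E <- cbind(starts, starts + exon_w)
    cursor[chrom] <- E[k, 2L]

    iso_range <- seq(config$isoforms_per_gene[1L],
                     config$isoforms_per_gene[2L])
    n_iso <- if (length(iso_range) == 1L) iso_range else sample(iso_range, 1L)
    primary_id <- paste0(gid, ".t1")
    txs <- list(transcript_model(primary_id, chrom, strand, E))
    iso_rows[[length(iso_rows) + 1L]] <-
      data.frame(id = primary_id, gene = gid, operator = "primary",
                 stringsAsFactors = FALSE)
    used_sites <- splice_chain(txs[[1L]])
    for (j in seq_len(n_iso - 1L)) {
      op <- sample(names(config$as_probs), 1L, prob = config$as_probs)
      res <- apply_as_operator(E, strand, op, used_sites)
      if (is.null(res)) next
      iso_id <- paste0(gid, ".t", length(txs) + 1L)
      new_tx <- transcript_model(iso_id, chrom, strand, res$exons)
      # an operator that reproduces an existing chain would break isoform
      # uniqueness; discard such draws
      if (any(vapply(txs, same_isoform, TRUE, t2 = new_tx))) next
      txs[[length(txs) + 1L]] <- new_tx
      used_sites <- union(used_sites, splice_chain(new_tx))
      ev <- res$event
      event_rows[[length(event_rows) + 1L]] <- data.frame(
        gene = gid, mode = ev$mode, major_type = ev$major_type,
        coords = ev$coords,
        isoform_in = if (ev$swap_in) iso_id else primary_id,
        isoform_out = if (ev$swap_in) primary_id else iso_id,
        stringsAsFactors = FALSE)
      iso_rows[[length(iso_rows) + 1L]] <-
        data.frame(id = iso_id, gene = gid, operator = op,
                   stringsAsFactors = FALSE)
    }
    loci[[gid]] <- gene_locus(gid, txs)
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene = gid, chrom = chrom, strand = strand,
      start = loci[[gid]]$start, end = loci[[gid]]$end,
      n_isoforms = length(txs), stringsAsFactors = FALSE)
  }
  empty_events <- data.frame(gene = character(0), mode = character(0),
                             major_type = character(0), coords = character(0),
                             isoform_in = character(0),
                             isoform_out = character(0),
                             stringsAsFactors = FALSE)
  list(annotation = annotation(unname(loci)),
       truth = list(
         genes = do.call(rbind, c(gene_rows, make.row.names = FALSE)),
         isoforms = do.call(rbind, c(iso_rows, make.row.names = FALSE)),
         events = if (length(event_rows))
           do.call(rbind, c(event_rows, make.row.names = FALSE))
         else empty_events))
}

# helper: exact FLNC copy of a reference transcript
flnc_copy <- function(t, id, pid, support, ngs = TRUE,
                      source_sample = NA_character_) {
  transcript_model(id, t$chrom, t$strand, t$exons, pid = pid,
                   flnc_support = support, ngs_support = ngs,
                   source_sample = source_sample)
}

# perturb one internal splice site of t to a position absent from used_sites;
# returns list(exons, junction_index) or NULL
perturb_splice_site <- function(t, used_sites) {
  E <- t$exons; k <- nrow(E)
  if (k < 2L) return(NULL)
  for (j in sample(k - 1L)) {
    r <- E[j + 1L, 1L]
    lo <- max(E[j, 2L] + 10, r - 50)
    hi <- min(E[j + 1L, 2L] - 20, r + 50)
    if (lo > hi) next
    cand <- setdiff(seq(lo, hi), c(used_sites, r))
    if (!length(cand)) next
    E2 <- E
    E2[j + 1L, 1L] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    return(list(exons = E2, junction = j))
  }
  NULL
}

#' Generate an FLNC transcript set with planted corruptions
#'
#' Emits an exact, NGS-supported copy of every reference transcript plus, at
#' the configured per-gene rates, corrupted variants with unambiguous truth
#' labels (each reference gene hosts at most one corruption):
#' \describe{
#'   \item{degraded_5p}{leading exon(s) on the transcript's 5' side removed
#'     (the rightmost genomic exons on minus-strand transcripts).}
#'   \item{structure_subset}{a contiguous interior run of exons, so splice
#'     sites are missing on both sides.}
#'   \item{duplicate}{the same splice chain with trimmed terminal exons (a
#'     shorter same-isoform copy).}
#'   \item{low_pid_singleton}{one perturbed splice site, PID below 99, FLNC
#'     support 1, the perturbed junction lacking NGS support.}
#'   \item{novel_isoform}{one perturbed (new) splice site at high PID with
#'     NGS support -- a genuine unannotated isoform.}
#'   \item{novel_gene}{a fresh transcript placed in an intergenic gap
#'     (zero overlap with annotated genes).}
#'   \item{antisense}{a transcript inside an annotated gene's span on the
#'     opposite strand.}
#'   \item{fusion}{a two-segment transcript whose segments copy transcripts
#'     of two distinct genes (inter- or intra-chromosomal), returned
#'     separately as segment pairs for the fusion detector.}
#' }
#'
#' @param reference Result of [simulate_reference()] (or its `annotation`).
#' @param config A [sim_config()].
#' @return List with `transcripts` (list of `transcript_model`), `fusions`
#'   (list of fusion candidates: `id`, `flnc_support`, `segments`), and
#'   `truth` (data frame: `id`, `label`, `source_tx`, `source_gene`,
#'   `expected`, plus `category` for fusions).
#' @export
simulate_flnc <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- if (inherits(reference, "annotation")) reference
         else reference$annotation
  set.seed(config$seed + 1L)
  out <- list(); truth <- list(); fusions <- list()
  add_truth <- function(id, label, src_tx, src_gene, expected,
                        category = NA_character_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, label = label, source_tx = src_tx, source_gene = src_gene,
      expected = expected, category = category, stringsAsFactors = FALSE)
  }

  # exact copies of every reference transcript
  gene_sites <- lapply(ann$loci, function(l)
    sort(unique(unlist(lapply(l$transcripts, splice_chain)))))
  for (l in ann$loci) for (t in l$transcripts) {
    id <- paste0("FL_", t$id)
    out[[id]] <- flnc_copy(t, id, pid = round(stats::runif(1, 99, 100), 2),
                           support = 1L + stats::rpois(1L, config$flnc_lambda))
    add_truth(id, "exact_match", t$id, l$id, "kept")
  }

  n_of <- function(rate) round(rate * n_loci(ann))
  gene_pool <- names(ann$loci)
  pick_gene <- function(eligible) {
    ok <- intersect(gene_pool, eligible)
    if (!length(ok)) return(NA_character_)
    g <- if (length(ok) == 1L) ok else sample(ok, 1L)
    gene_pool <<- setdiff(gene_pool, g)
    g
  }
  genes_with <- function(pred) {
    names(ann$loci)[vapply(ann$loci, function(l)
      any(vapply(l$transcripts, pred, TRUE)), TRUE)]
  }

  # 5'-degraded copies: drop leading exons on the transcript's 5' side
  for (i in seq_len(n_of(config$degraded_rate))) {
    g <- pick_gene(genes_with(function(t) n_exons(t) >= 3L))
    if (is.na(g)) break
    l <- ann$loci[[g]]
    cands <- Filter(function(t) n_exons(t) >= 3L, l$transcripts)
    t <- cands[[sample(length(cands), 1L)]]
    k <- n_exons(t)
    d <- sample(k - 2L, 1L)  # keep >= 2 exons so the chain stays non-empty
    E <- if (t$strand == "+") t$exons[-seq_len(d), , drop = FALSE]
         else t$exons[seq_len(k - d), , drop = FALSE]
    id <- paste0("DEG_", t$id)
    out[[id]] <- transcript_model(id, t$chrom, t$strand, E,
                                  pid = round(stats::runif(1, 99, 100), 2),
                                  flnc_support = 1L)
    add_truth(id, "degraded_5p", t$id, g, "degraded_5p")
  }

  # structure subsets: contiguous interior exon runs
  for (i in seq_len(n_of(config$subset_rate))) {
    g <- pick_gene(genes_with(function(t) n_exons(t) >= 4L))
    if (is.na(g)) break
    l <- ann$loci[[g]]
    cands <- Filter(function(t) n_exons(t) >= 4L, l$transcripts)
    t <- cands[[sample(length(cands), 1L)]]
    k <- n_exons(t)
    member_chains <- lapply(l$transcripts, splice_chain)
    for (attempt in 1:10) {
      i0 <- if (k == 4L) 2L else sample(2:(k - 2L), 1L)
      j0 <- if (i0 + 1L == k - 1L) k - 1L else sample((i0 + 1L):(k - 1L), 1L)
      sub <- transcript_model("tmp", t$chrom, t$strand,
                              t$exons[i0:j0, , drop = FALSE])
      # the run must be interior relative to every isoform chain of the gene,
      # otherwise the removal reason would be ambiguous (degraded vs subset)
      sc <- splice_chain(sub)
      edge <- any(vapply(member_chains, function(mc) {
        s <- chain_run_index(sc, mc)
        s == 1L || (s > 0L && s + length(sc) - 1L == length(mc))
      }, TRUE))
      if (!edge) break
      sub <- NULL
    }
    if (is.null(sub)) next
    id <- paste0("SUB_", t$id)
    out[[id]] <- transcript_model(id, t$chrom, t$strand,
                                  t$exons[i0:j0, , drop = FALSE],
                                  pid = round(stats::runif(1, 99, 100), 2),
                                  flnc_support = 1L)
    add_truth(id, "structure_subset", t$id, g, "structure_subset")
  }

  # shorter same-isoform duplicates: trim terminal exon ends
  for (i in seq_len(n_of(config$duplicate_rate))) {
    g <- pick_gene(genes_with(function(t) {
      E <- t$exons; k <- nrow(E)
      (E[1L, 2L] - E[1L, 1L] > 30) && (E[k, 2L] - E[k, 1L] > 30)
    }))
    if (is.na(g)) break
    l <- ann$loci[[g]]
    cands <- Filter(function(t) {
      E <- t$exons; k <- nrow(E)
      (E[1L, 2L] - E[1L, 1L] > 30) && (E[k, 2L] - E[k, 1L] > 30)
    }, l$transcripts)
    t <- cands[[sample(length(cands), 1L)]]
    E <- t$exons; k <- nrow(E)
    E[1L, 1L] <- E[1L, 1L] + sample(5:20, 1L)
    E[k, 2L] <- E[k, 2L] - sample(5:20, 1L)
    id <- paste0("DUP_", t$id)
    out[[id]] <- transcript_model(id, t$chrom, t$strand, E,
                                  pid = round(stats::runif(1, 99, 100), 2),
                                  flnc_support = 1L)
    add_truth(id, "duplicate", t$id, g, "duplicate_shorter")
  }

  # low-PID singletons: perturbed splice site, no NGS support, one read
  for (i in seq_len(n_of(config$low_pid_rate))) {
    g <- pick_gene(genes_with(function(t) n_exons(t) >= 2L))
    if (is.na(g)) break
    l <- ann$loci[[g]]
    cands <- Filter(function(t) n_exons(t) >= 2L, l$transcripts)
    t <- cands[[sample(length(cands), 1L)]]
    pert <- perturb_splice_site(t, gene_sites[[g]])
    if (is.null(pert)) next
    id <- paste0("LOWPID_", t$id)
    ngs <- rep(TRUE, nrow(pert$exons) - 1L)
    ngs[pert$junction] <- FALSE
    out[[id]] <- transcript_model(
      id, t$chrom, t$strand, pert$exons,
      pid = round(stats::runif(1, config$low_pid_range[1L],
                               config$low_pid_range[2L]), 2),
      flnc_support = 1L, ngs_support = ngs)
    add_truth(id, "low_pid_singleton", t$id, g, "low_pid_unsupported")
  }

  # novel isoforms: a new splice site at high PID with NGS support
  for (i in seq_len(n_of(config$novel_isoform_rate))) {
    g <- pick_gene(genes_with(function(t) n_exons(t) >= 2L))
    if (is.na(g)) break
    l <- ann$loci[[g]]
    cands <- Filter(function(t) n_exons(t) >= 2L, l$transcripts)
    t <- cands[[sample(length(cands), 1L)]]
    pert <- perturb_splice_site(t, gene_sites[[g]])
    if (is.null(pert)) next
    id <- paste0("NOVISO_", t$id)
    out[[id]] <- transcript_model(id, t$chrom, t$strand, pert$exons,
                                  pid = round(stats::runif(1, 99, 100), 2),
                                  flnc_support = 2L)
    add_truth(id, "novel_isoform", t$id, g, "kept")
  }

  # novel genes: fresh structures in intergenic gaps
  gaps <- intergenic_gaps(ann)
  gaps <- gaps[gaps$end - gaps$start >= 1500, , drop = FALSE]
  n_novel <- min(n_of(config$novel_gene_rate), nrow(gaps))
  if (n_novel > 0L) {
    rows <- sample(nrow(gaps), n_novel)
    for (i in seq_len(n_novel)) {
      gp <- gaps[rows[i], ]
      k <- sample(1:3, 1L)
      exon_w <- rint(k, c(100L, 250L))
      intron_w <- if (k > 1L) rint(k - 1L, c(80L, 150L)) else integer(0)
      need <- sum(exon_w) + sum(intron_w)
      if (gp$end - gp$start - 400 < need) { k <- 1L; exon_w <- 200L
                                            intron_w <- integer(0)
                                            need <- 200L }
      start <- gp$start + 200
      starts <- start + c(0, cumsum(exon_w[-k] + intron_w))
      id <- sprintf("NOVGENE_%03d", i)
      out[[id]] <- transcript_model(id, gp$chrom, sample(c("+", "-"), 1L),
                                    cbind(starts, starts + exon_w),
                                    pid = round(stats::runif(1, 99, 100), 2),
                                    flnc_support = 2L)
      add_truth(id, "novel_gene", NA_character_, NA_character_, "kept")
    }
  }

  # antisense transcripts: inside an annotated gene, opposite strand
  for (i in seq_len(n_of(config$antisense_rate))) {
    g <- pick_gene(names(ann$loci)[vapply(ann$loci, function(l)
      l$end - l$start >= 600, TRUE)])
    if (is.na(g)) break
    l <- ann$loci[[g]]
    w <- l$end - l$start
    s0 <- l$start + round(0.2 * w)
    id <- paste0("ANTI_", g)
    out[[id]] <- transcript_model(id, l$chrom,
                                  if (l$strand == "+") "-" else "+",
                                  cbind(s0, s0 + round(0.6 * w)),
                                  pid = round(stats::runif(1, 99, 100), 2),
                                  flnc_support = 2L)
    add_truth(id, "antisense", NA_character_, g, "kept")
  }

  # fusion transcripts: two segments copying transcripts of distinct genes
  n_fus <- n_of(config$fusion_rate)
  if (n_fus > 0L && n_loci(ann) >= 2L) {
    for (i in seq_len(n_fus)) {
      pair <- sample(names(ann$loci), 2L)
      segs <- lapply(seq_along(pair), function(j) {
        t <- ann$loci[[pair[j]]]$transcripts[[1L]]
        flnc_copy(t, sprintf("FUS%03d_seg%d", i, j), 99.5, 1L)
      })
      id <- sprintf("FUS%03d", i)
      support <- sample(1:3, 1L)
      chroms <- vapply(ann$loci[pair], `[[`, "", "chrom")
      fusions[[id]] <- list(id = id, flnc_support = support, segments = segs)
      add_truth(id, "fusion", NA_character_, paste(sort(pair), collapse = ","),
                "fusion",
                category = if (length(unique(chroms)) > 1L) "inter_chromosome"
                           else "intra_chromosome")
    }
  }

  truth_df <- if (length(truth))
    do.call(rbind, c(truth, make.row.names = FALSE))
  else data.frame(id = character(0), label = character(0),
                  source_tx = character(0), source_gene = character(0),
                  expected = character(0), category = character(0),
                  stringsAsFactors = FALSE)
  list(transcripts = out, fusions = fusions, truth = truth_df)
}

# gaps between annotated loci per chromosome (plus a tail gap)
intergenic_gaps <- function(ann) {
  idx <- ann$index
  rows <- list()
  for (ch in unique(idx$chrom)) {
    sub <- idx[idx$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L) {
      for (i in seq_len(nrow(sub) - 1L)) {
        if (sub$start[i + 1L] > sub$end[i])
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, start = sub$end[i], end = sub$start[i + 1L],
            stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, start = max(sub$end), end = max(sub$end) + 1e5,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Generate a negative-binomial count matrix with planted fold changes
#'
#' One count matrix over the full factorial design (varieties x treatments x
#' replicates, with the `<variety>-<treatment><replicate>` sample labels). A
#' `de_fraction` of genes receive a planted log2 fold change applied to the
#' treatment columns of both varieties; counts are drawn negative-binomial
#' with gene-level base means, per-sample library factors within 2x of each
#' other, and the configured dispersion (Poisson when 0). Gene lengths are
#' the exonic length of each locus's longest isoform.
#'
#' @param ann Reference or collapsed [annotation()] supplying gene ids and
#'   lengths.
#' @param config A [sim_config()].
#' @return List with `em` (an [expression_matrix()]) and `truth` (data
#'   frame: `gene`, `is_de`, `log2fc`).
#' @export
simulate_counts <- function(ann, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genes <- names(ann$loci)
  n <- length(genes)
  lengths <- vapply(ann$loci, function(l)
    max(vapply(l$transcripts, exon_length_sum, 0)), 0)
  design <- expand.grid(replicate = seq_len(config$n_reps),
                        treatment = config$treatments,
                        variety = config$varieties,
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s-%s%d", design$variety, design$treatment,
                           design$replicate)
  design <- design[, c("sample", "variety", "treatment", "replicate")]

  base_mean <- exp(stats::runif(n, log(config$nb_mean_range[1L]),
                                log(config$nb_mean_range[2L])))
  is_de <- rep(FALSE, n)
  lfc <- rep(0, n)
  n_de <- round(config$de_fraction * n)
  if (n_de > 0L) {
    de_idx <- sample(n, n_de)
    is_de[de_idx] <- TRUE
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, config$de_log2fc_range[1L],
                   config$de_log2fc_range[2L])
  }
  lib_factor <- exp(stats::runif(nrow(design), 0, log(2)))
  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(genes, design$sample))
  for (s in seq_len(nrow(design))) {
    mu <- base_mean * lib_factor[s] *
      (if (design$treatment[s] == config$treatments[1L]) 2^lfc else rep(1, n))
    counts[, s] <- if (config$nb_dispersion <= 1e-8) stats::rpois(n, mu)
                   else stats::rnbinom(n, mu = mu,
                                       size = 1 / config$nb_dispersion)
  }
  em <- expression_matrix(counts, stats::setNames(lengths, genes), design)
  list(em = em,
       truth = data.frame(gene = genes, is_de = is_de, log2fc = lfc,
                          stringsAsFactors = FALSE, row.names = NULL))
}
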