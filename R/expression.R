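#' Construct a gene-by-sample expression matrix
#'
#' @param counts Non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param gene_lengths Named numeric vector of gene model lengths in bp.
#' @param design Data frame with one row per sample: columns `sample` (the
#'   column label), plus arbitrary grouping columns (e.g. `variety`,
#'   `treatment`, `replicate`).
#' @param library_sizes Total mapped reads per sample; defaults to column
#'   sums.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_lengths, design,
                              library_sizes = colSums(counts)) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  gene_lengths <- gene_lengths[rownames(counts)]
  if (anyNA(gene_lengths) || any(gene_lengths <= 0))
    stop("every gene needs a positive length")
  if (any(counts < 0)) stop("negative counts")
  if (!all(colnames(counts) == design$sample))
    stop("design rows must match count columns in order")
  if (any(library_sizes < colSums(counts)))
    stop("library sizes smaller than column sums")
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 design = design,
                 library_sizes = stats::setNames(library_sizes,
                                                 colnames(counts))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm[g, s] = counts[g, s] * 1e9 / (gene_length[g] * library_size[s])`.
#' The quantity is invariant under joint scaling of counts and library sizes
#' and halves in a column when that library size doubles.
#'
#' @param em An [expression_matrix()].
#' @return Numeric matrix of RPKM values, same dimensions as the counts.
#' @examples
#' em <- expression_matrix(matrix(10, 1, 1, dimnames = list("g", "s")),
#'                         c(g = 1000), data.frame(sample = "s"),
#'                         library_sizes = 1e6)
#' rpkm(em)  # 10
#' @export
rpkm <- function(em) {
  if (any(em$library_sizes == 0)) stop("zero library size")
  em$counts * 1e9 / outer(em$gene_lengths, em$library_sizes)
}

#' Per-gene two-sample t-test on log2 expression
#'
#' For each gene, a two-sample t-test on `log2(RPKM + pseudocount)` between
#' two sample groups. The log2 fold change is the difference of group means
#' on the log2 scale (A minus B). The default is the pooled-variance
#' (Student) test: with the typical 3-replicate design the Welch
#' approximation is markedly conservative (its empirical size at 3 vs 3 is
#' about 0.035 at nominal 0.05 even on exactly normal data), while the
#' pooled test holds its nominal level; set `welch = TRUE` for the
#' unequal-variance form. Genes with zero variance in both groups get
#' `p = 1` when the means are equal and `p = 0` (flagged `degenerate`) when
#' they differ.
#'
#' @param em An [expression_matrix()].
#' @param group_a,group_b Character vectors of sample (column) labels.
#' @param pseudocount Added before the log2 transform (default 1).
#' @param welch Use the Welch unequal-variance test instead of the pooled
#'   test (default `FALSE`).
#' @return Data frame with columns `gene`, `log2fc`, `mean_rpkm_a`,
#'   `mean_rpkm_b`, `p_value`, `degenerate`.
#' @export
deg_test <- function(em, group_a, group_b, pseudocount = 1, welch = FALSE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  r <- rpkm(em)
  xa <- log2(r[, group_a, drop = FALSE] + pseudocount)
  xb <- log2(r[, group_b, drop = FALSE] + pseudocount)
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & ma == mb] <- 1
  p[degenerate & ma != mb] <- 0
  data.frame(gene = rownames(r), log2fc = unname(ma - mb),
             mean_rpkm_a = unname(rowMeans(r[, group_a, drop = FALSE])),
             mean_rpkm_b = unname(rowMeans(r[, group_b, drop = FALSE])),
             p_value = unname(p), degenerate = unname(degenerate),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of p-values; a thin wrapper around
#' `p.adjust(method = "BH")` so the pipeline's multiple-testing step is
#' explicit and testable against a brute-force implementation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Applies the three gates conjunctively: FDR at most `max_fdr`, absolute
#' log2 fold change at least `min_abs_log2fc`, and maximum group-mean RPKM at
#' least `min_rpkm`. Genes passing all three are called `up` or `down` by the
#' sign of the fold change; everything else is `not_de`.
#'
#' @param stats Data frame from [deg_test()].
#' @param min_rpkm RPKM floor on the larger group mean (default 0.1).
#' @param min_abs_log2fc Fold-change gate on the log2 scale (default 2; use
#'   `1` for the fold-change-of-2 reading).
#' @param max_fdr FDR gate (default 0.05; 0.01 is the stricter preset).
#' @return `stats` with added columns `fdr` and `call`.
#' @export
call_degs <- function(stats, min_rpkm = 0.1, min_abs_log2fc = 2,
                      max_fdr = 0.05) {
  stats$fdr <- bh_fdr(stats$p_value)
  pass <- stats$fdr <= max_fdr &
    abs(stats$log2fc) >= min_abs_log2fc &
    pmax(stats$mean_rpkm_a, stats$mean_rpkm_b) >= min_rpkm
  stats$call <- ifelse(pass, ifelse(stats$log2fc > 0, "up", "down"), "not_de")
  stats
}

#' Set algebra over named DEG lists
#'
#' Exact set operations on gene ids across comparisons: all pairwise
#' intersections, plus, when `treatment_comparison` and
#' `control_comparison` name two of the lists, the "remaining candidate"
#' subtraction (genes differentially expressed under treatment but not under
#' control).
#'
#' @param deg_lists Named list of character vectors of gene ids.
#' @param treatment_comparison,control_comparison Optional names within
#'   `deg_lists` for the candidate subtraction.
#' @return List with `sizes`, `pairwise` (data frame of intersection sizes
#'   and shared ids) and, when requested, `shared_t_ck` and `candidates`.
#' @export
deg_set_algebra <- function(deg_lists, treatment_comparison = NULL,
                            control_comparison = NULL) {
  stopifnot(length(deg_lists) >= 2L, !is.null(names(deg_lists)))
  deg_lists <- lapply(deg_lists, function(x) sort(unique(x)))
  nm <- names(deg_lists)
  pairs <- utils::combn(nm, 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    sh <- intersect(deg_lists[[a]], deg_lists[[b]])
    data.frame(a = a, b = b, n_shared = length(sh),
               shared = paste(sh, collapse = ","), stringsAsFactors = FALSE)
  }))
  out <- list(sizes = lengths(deg_lists), pairwise = pairwise)
  if (!is.null(treatment_comparison) && !is.null(control_comparison)) {
    t_set <- deg_lists[[treatment_comparison]]
    ck_set <- deg_lists[[control_comparison]]
    out$shared_t_ck <- intersect(t_set, ck_set)
    out$candidates <- setdiff(t_set, ck_set)
  }
  out
}

#' Hypergeometric enrichment of DEG sets in annotation terms
#'
#' Upper-tail hypergeometric test per term: with `N` background genes of
#' which `K` carry the term, and `n` DE genes of which `k` carry it, the
#' p-value is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, followed by
#' Benjamini-Hochberg adjustment across terms.
#'
#' @param de_genes Character vector of DE gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of background gene ids (the whole
#'   transcriptome).
#' @param term_map Named list: term id -> character vector of member genes
#'   (intersected with the background).
#' @return Data frame with columns `term`, `k`, `n`, `K`, `N`, `p_value`,
#'   `fdr`, sorted by p-value.
#' @export
hypergeom_enrich <- function(de_genes, background, term_map) {
  de_genes <- unique(de_genes); background <- unique(background)
  bad <- setdiff(de_genes, background)
  if (length(bad))
    stop("DE genes absent from background: ", paste(bad, collapse = ", "))
  N <- length(background); n <- length(de_genes)
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(term_map[[tm]], background)
    K <- length(members)
    k <- length(intersect(de_genes, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$fdr <- bh_fdr(out$p_value)
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Relative expression by the 2^-ddCt method
#'
#' For each gene and sample, `dCt = Ct_target - Ct_reference` is averaged
#' over replicates; `ddCt = dCt_sample - dCt_calibrator`; relative expression
#' is `2^-ddCt`, so the calibrator sample's own value is 1.
#'
#' @param ct Data frame with columns `gene`, `sample`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @param calibrator Sample label used as the calibrator.
#' @return Data frame with columns `gene`, `sample`, `dct`, `ddct`,
#'   `rel_expr`.
#' @export
delta_delta_ct <- function(ct, calibrator) {
  need <- c("gene", "sample", "replicate", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct)))
  if (anyNA(ct$ct_reference))
    stop("missing reference-gene Ct value(s)")
  if (!calibrator %in% ct$sample)
    stop("calibrator sample not present: ", calibrator)
  ct$dct_rep <- ct$ct_target - ct$ct_reference
  agg <- stats::aggregate(dct_rep ~ gene + sample, data = ct, FUN = mean)
  names(agg)[names(agg) == "dct_rep"] <- "dct"
  cal <- agg[agg$sample == calibrator, c("gene", "dct")]
  names(cal)[2L] <- "dct_cal"
  out <- merge(agg, cal, by = "gene")
  out$ddct <- out$dct - out$dct_cal
  out$rel_expr <- 2^(-out$ddct)
  out <- out[order(out$gene, out$sample),
             c("gene", "sample", "dct", "ddct", "rel_expr")]
  rownames(out) <- NULL
  out
}
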