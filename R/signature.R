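# Divergent-gene and signature-gene selection, unsupervised hierarchical
# clustering, and the candidate miRNA-target workflow. Fold thresholds
# (1.5, 1.3) are linear ratios applied on the log2 scale, i.e. a gene
# passes when |log2 deviation| >= log2(threshold); comparisons are
# inclusive throughout so the rule is fixed one way.

#' Genes divergent from the gene-wise median
#'
#' Per gene the deviation of an experiment is the mean, over the
#' experiment's samples, of (log2 value - gene median across all
#' samples). A gene is selected when its absolute deviation reaches
#' log2(fold_threshold) in at least `min_experiments` experiments.
#'
#' @param x an `ExpressionMatrix`
#' @param experiments named list of sample-id vectors, one per
#'   experiment; defaults to the matrix's condition groups
#' @param fold_threshold linear fold-ratio threshold (> 1), default 1.5
#' @param min_experiments minimum experiments passing, default 1
#' @return character vector of selected genes (input order)
#' @export
divergent_genes <- function(x, experiments = NULL, fold_threshold = 1.5,
                            min_experiments = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (fold_threshold <= 1) stop("'fold_threshold' must be > 1")
  if (is.null(experiments))
    experiments <- split(colnames(x$values), x$condition)
  med <- apply(x$values, 1, stats::median)
  dev <- vapply(experiments, function(smp)
    rowMeans(x$values[, smp, drop = FALSE]) - med,
    numeric(nrow(x$values)))
  passes <- rowSums(abs(dev) >= log2(fold_threshold))
  sel <- rownames(x$values)[passes >= min_experiments]
  message(sprintf(
    "divergent_genes (fold >= %g in >= %d of %d experiments): %d of %d genes",
    fold_threshold, min_experiments, length(experiments), length(sel),
    nrow(x$values)))
  sel
}

#' Signature genes recurrent across oriented contrasts
#'
#' Selects genes whose oriented log2 fold change reaches
#' log2(fold_threshold) in at least `min_experiments` contrasts, with a
#' consistent direction across the passing contrasts (switchable).
#' Orientations point every contrast toward the nc886-high direction, so
#' a knockdown contrast is supplied with orientation -1.
#'
#' @param contrasts named list of `ContrastResult`s
#' @param orientations numeric +1/-1 per contrast
#' @param fold_threshold linear fold-ratio threshold, default 1.3
#' @param min_experiments minimum passing contrasts, default 3
#' @param sign_consistent require one direction across passing contrasts
#' @return data frame of class `SignatureGeneList`: `gene`, one oriented
#'   `fc.<name>` column per contrast, `n_pass`, `sign`; attribute `rule`
#'   records the thresholds verbatim.
#' @export
signature_genes <- function(contrasts,
                            orientations = rep(1, length(contrasts)),
                            fold_threshold = 1.3, min_experiments = 3,
                            sign_consistent = TRUE) {
  if (length(contrasts) == 0) stop("no contrasts supplied")
  if (fold_threshold <= 1) stop("'fold_threshold' must be > 1")
  if (length(orientations) != length(contrasts) ||
      !all(orientations %in% c(-1, 1)))
    stop("need one +1/-1 orientation per contrast")
  if (is.null(names(contrasts)))
    names(contrasts) <- paste0("exp", seq_along(contrasts))
  shared <- Reduce(intersect, lapply(contrasts, `[[`, "gene"))
  fc <- vapply(seq_along(contrasts), function(k) {
    ct <- contrasts[[k]]
    orientations[k] * ct$fc[match(shared, ct$gene)]
  }, numeric(length(shared)))
  colnames(fc) <- names(contrasts)
  cut <- log2(fold_threshold)
  pass <- abs(fc) >= cut
  n_pass <- rowSums(pass)
  keep <- n_pass >= min_experiments
  if (sign_consistent) {
    consistent <- vapply(seq_along(shared), function(i) {
      s <- sign(fc[i, pass[i, ]])
      length(unique(s)) <= 1
    }, TRUE)
    keep <- keep & consistent
  }
  sgn <- vapply(seq_along(shared), function(i) {
    s <- sign(fc[i, pass[i, ]])
    if (length(s) == 0) 0 else as.numeric(names(sort(table(s),
                                                     decreasing = TRUE))[1])
  }, 1)
  res <- data.frame(gene = shared[keep],
                    fc[keep, , drop = FALSE],
                    n_pass = n_pass[keep], sign = sgn[keep],
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  message(sprintf(
    "signature_genes (|fc| >= log2(%g) in >= %d of %d contrasts%s): %d genes",
    fold_threshold, min_experiments, length(contrasts),
    if (sign_consistent) ", sign-consistent" else "", nrow(res)))
  structure(res, class = c("SignatureGeneList", "data.frame"),
            rule = list(fold_threshold = fold_threshold,
                        min_experiments = min_experiments,
                        sign_consistent = sign_consistent))
}

#' Export a signature gene list as a one-set collection
#' @param sig a `SignatureGeneList`
#' @param name set name for the export
#' @return a [gene_set_collection()] with a single set
#' @export
signature_to_collection <- function(sig, name = "SIGNATURE") {
  stopifnot(inherits(sig, "SignatureGeneList"))
  gene_set_collection(stats::setNames(list(sig$gene), name), name)
}

#' Unsupervised hierarchical clustering of genes and samples
#'
#' Values are median-centered per gene; the distance is 1 - Pearson
#' correlation; linkage is average (UPGMA), agglomerating genes and
#' samples independently. The two-group sample partition cuts the sample
#' dendrogram at its last merge. Genes (or samples) left without
#' variance after centering are dropped with a message.
#'
#' @param x an `ExpressionMatrix`
#' @param genes optional gene subset (e.g. a divergent-gene list)
#' @return list of class `ClusteringResult`: `gene_hclust`,
#'   `sample_hclust`, `gene_order`, `sample_order`, `partition` (named
#'   1/2 per sample)
#' @export
hierarchical_cluster <- function(x, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(v))
    v <- v[genes, , drop = FALSE]
  }
  if (nrow(v) < 2 || ncol(v) < 2) stop("need >= 2 genes and >= 2 samples")
  centered <- v - apply(v, 1, stats::median)
  gvar <- .row_vars(centered)
  if (any(gvar == 0)) {
    message(sprintf("dropping %d zero-variance gene(s)", sum(gvar == 0)))
    centered <- centered[gvar > 0, , drop = FALSE]
    if (nrow(centered) < 2) stop("fewer than 2 genes with variance")
  }
  gene_d <- stats::as.dist(1 - stats::cor(t(centered)))
  sample_d <- stats::as.dist(1 - stats::cor(centered))
  gene_hc <- stats::hclust(gene_d, method = "average")
  sample_hc <- stats::hclust(sample_d, method = "average")
  structure(list(gene_hclust = gene_hc, sample_hclust = sample_hc,
                 gene_order = gene_hc$labels[gene_hc$order],
                 sample_order = sample_hc$labels[sample_hc$order],
                 partition = stats::cutree(sample_hc, k = 2)),
            class = "ClusteringResult")
}

#' Candidate miRNA-target genes from opposed contrasts
#'
#' Genes significantly decreased in the knockdown contrast but increased
#' in the induced (e.g. TGF-beta) contrast, then intersected with the
#' union of member genes of the selected MIR sets — the direction
#' expected of genes relieved from miRNA repression when nc886 is high.
#'
#' @param kd_contrast `ContrastResult` of the knockdown experiment
#' @param induced_contrast `ContrastResult` of the inducing experiment
#' @param mir_sets `GeneSetCollection` (or named list of member vectors)
#'   of the selected MIR sets; must be non-empty
#' @param p_cut per-contrast significance threshold
#' @return character vector of candidate target genes
#' @export
candidate_targets <- function(kd_contrast, induced_contrast, mir_sets,
                              p_cut = 0.05) {
  stopifnot(inherits(kd_contrast, "ContrastResult"),
            inherits(induced_contrast, "ContrastResult"))
  if (inherits(mir_sets, "GeneSetCollection")) mir_sets <- mir_sets$sets
  if (length(mir_sets) == 0) stop("empty MIR set selection")
  members <- unique(toupper(unlist(mir_sets, use.names = FALSE)))
  if (length(members) == 0) stop("empty MIR set selection")
  m <- merge(kd_contrast[, c("gene", "fc", "p")],
             induced_contrast[, c("gene", "fc", "p")],
             by = "gene", suffixes = c("_kd", "_ind"))
  sel <- m$p_kd < p_cut & m$p_ind < p_cut & m$fc_kd < 0 & m$fc_ind > 0
  opposed <- m$gene[sel]
  out <- opposed[toupper(opposed) %in% members]
  message(sprintf(
    "candidate_targets: %d opposed genes (down in kd, up in induced), %d in MIR sets",
    length(opposed), length(out)))
  out
}
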