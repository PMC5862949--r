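# Per-gene two-sample contrasts and the selection / comparison rules
# applied to them.

.row_vars <- function(m) {
  rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
}

# Pearson r plus the p-value of the simple-linear-regression F statistic
# (identical to the two-sided correlation test: t^2 = F with 1, n-2 df).
.pearson_f <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  if (is.na(r) || abs(r) >= 1) {
    p <- if (is.na(r)) NA_real_ else 0
  } else {
    f <- r^2 * (n - 2) / (1 - r^2)
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Per-gene contrast between two conditions
#'
#' For every gene: log2 fold change (mean treatment minus mean reference),
#' the two-sample t statistic on log2 values, and its two-sided p-value.
#' The default is the classical pooled-variance Student t with
#' n1 + n2 - 2 degrees of freedom; Welch is available via `var_equal =
#' FALSE`. Genes where both groups have zero variance and equal means get
#' t = 0, p = 1; zero pooled variance with unequal means is flagged
#' `degenerate` and excluded by [select_significant()].
#'
#' @param x an `ExpressionMatrix`
#' @param treatment,reference condition labels, each with >= 2 replicates
#' @param var_equal pooled-variance Student t (default) or Welch
#' @return data frame of class `ContrastResult` with columns `gene`,
#'   `fc`, `t`, `p`, `degenerate` and attributes `contrast_name`,
#'   `n_treatment`, `n_reference`, `df`.
#' @export
contrast <- function(x, treatment, reference, var_equal = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  it <- which(x$condition == treatment)
  ir <- which(x$condition == reference)
  if (length(it) < 2)
    stop("condition '", treatment, "' has fewer than 2 replicates")
  if (length(ir) < 2)
    stop("condition '", reference, "' has fewer than 2 replicates")
  mt <- x$values[, it, drop = FALSE]
  mr <- x$values[, ir, drop = FALSE]
  nt <- length(it); nr <- length(ir)
  fc <- rowMeans(mt) - rowMeans(mr)
  vt <- .row_vars(mt); vr <- .row_vars(mr)
  if (var_equal) {
    df <- nt + nr - 2
    sp2 <- ((nt - 1) * vt + (nr - 1) * vr) / df
    se <- sqrt(sp2 * (1 / nt + 1 / nr))
    dfs <- rep(df, length(fc))
  } else {
    se <- sqrt(vt / nt + vr / nr)
    dfs <- (vt / nt + vr / nr)^2 /
      ((vt / nt)^2 / (nt - 1) + (vr / nr)^2 / (nr - 1))
    df <- NA_real_
  }
  t <- fc / se
  degenerate <- se == 0 & fc != 0
  t[se == 0 & fc == 0] <- 0
  t[degenerate] <- sign(fc[degenerate]) * Inf
  p <- 2 * stats::pt(-abs(t), dfs)
  p[se == 0 & fc == 0] <- 1
  p[degenerate] <- 0
  res <- data.frame(gene = rownames(x$values), fc = fc, t = t, p = p,
                    degenerate = degenerate, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(res,
            class = c("ContrastResult", "data.frame"),
            contrast_name = paste(treatment, "vs", reference),
            n_treatment = nt, n_reference = nr, df = df)
}

#' Select significant genes by p-value and fold-change cutoffs
#'
#' Keeps genes with p below `p_cut` and absolute log2 fold change of at
#' least `fc_cut`, in input order. Degenerate genes (zero pooled variance
#' with unequal means) are excluded.
#'
#' @param ct a `ContrastResult`
#' @param p_cut raw p-value threshold (default 0.05)
#' @param fc_cut absolute log2 fold-change threshold (default 0.5)
#' @return character vector of gene symbols
#' @export
select_significant <- function(ct, p_cut = 0.05, fc_cut = 0.5) {
  stopifnot(inherits(ct, "ContrastResult"))
  if (p_cut <= 0 || fc_cut < 0) stop("thresholds must be positive")
  keep <- ct$p < p_cut & abs(ct$fc) >= fc_cut & !ct$degenerate
  message(sprintf("select_significant (p < %g, |fc| >= %g): %d of %d genes",
                  p_cut, fc_cut, sum(keep), nrow(ct)))
  ct$gene[keep]
}

#' Venn counts of two gene lists
#'
#' @param a,b character vectors of gene symbols (deduplicated internally)
#' @return named integer vector `c(a_only, both, b_only)`
#' @export
venn <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- length(intersect(a, b))
  c(a_only = length(a) - both, both = both, b_only = length(b) - both)
}

#' Correlate fold changes of two contrasts over jointly significant genes
#'
#' Restricts to genes with p below `p_cut` in both contrasts (no
#' fold-change cutoff), then reports the Pearson correlation of the fold
#' changes with the p-value of the regression F statistic.
#'
#' @param ca,cb `ContrastResult`s sharing a gene universe
#' @param p_cut per-contrast significance threshold
#' @return list of class `CorrelationReport`: `gene_count`, `pearson_r`,
#'   `p_value`, `selection_rule`
#' @export
correlate_contrasts <- function(ca, cb, p_cut = 0.05) {
  stopifnot(inherits(ca, "ContrastResult"), inherits(cb, "ContrastResult"))
  m <- merge(ca[, c("gene", "fc", "p")], cb[, c("gene", "fc", "p")],
             by = "gene", suffixes = c("_a", "_b"))
  m <- m[m$p_a < p_cut & m$p_b < p_cut, ]
  if (nrow(m) < 3)
    stop("fewer than 3 genes significant in both contrasts; ",
         "correlation undefined")
  pf <- .pearson_f(m$fc_a, m$fc_b)
  structure(list(gene_count = nrow(m), pearson_r = pf$r, p_value = pf$p,
                 selection_rule = sprintf("p < %g in both contrasts",
                                          p_cut)),
            class = "CorrelationReport")
}

#' @export
print.CorrelationReport <- function(x, ...) {
  cat(sprintf("CorrelationReport: %d genes, Pearson r = %.4f, p = %.3g\n",
              x$gene_count, x$pearson_r, x$p_value))
  cat("  selection:", x$selection_rule, "\n")
  invisible(x)
}

#' Write a contrast table as CSV
#' @param ct a `ContrastResult`
#' @param path output path
#' @param p_cut,fc_cut thresholds used for the `selected` flag column
#' @export
write_contrast <- function(ct, path, p_cut = 0.05, fc_cut = 0.5) {
  df <- as.data.frame(ct)
  df$selected <- df$p < p_cut & abs(df$fc) >= fc_cut & !df$degenerate
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
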