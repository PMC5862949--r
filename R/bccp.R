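# Bayesian Compound Covariate Predictor: signature genes are weighted by
# their two-sample t statistics on standardized training values; the
# weighted sum (compound covariate) is modelled as a Gaussian per class,
# and a sample's posterior probability of the nc886-high class follows
# from Bayes' rule. Equal priors by default: the training set is a
# designed experiment panel, not a population sample.

.resolve_genes <- function(genes) {
  if (inherits(genes, "SignatureGeneList")) genes <- genes$gene
  unique(as.character(genes))
}

.pooled_t <- function(m, grp_a, grp_b) {
  # rows = genes; returns pooled-variance two-sample t (a minus b)
  ma <- m[, grp_a, drop = FALSE]; mb <- m[, grp_b, drop = FALSE]
  na <- ncol(ma); nb <- ncol(mb)
  d <- rowMeans(ma) - rowMeans(mb)
  sp2 <- ((na - 1) * .row_vars(ma) + (nb - 1) * .row_vars(mb)) /
    (na + nb - 2)
  d / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Fit a Bayesian Compound Covariate Predictor
#'
#' @param x training `ExpressionMatrix`
#' @param labels named character vector, `"high"` or `"low"` per training
#'   sample; both classes need >= 2 samples
#' @param genes signature genes (character vector or
#'   `SignatureGeneList`); genes absent from the matrix are dropped with
#'   a message
#' @param priors class priors, `c(high = , low = )`, default equal
#' @param cutoffs posterior cutoffs for the tri-state call,
#'   `c(low = 0.3, high = 0.7)`
#' @return object of class `BCCPModel`: per-gene weights `t` and training
#'   standardization constants, class means `m_high`/`m_low` of the
#'   compound covariate, pooled within-class variance `s2`, priors and
#'   cutoffs
#' @export
bccp_fit <- function(x, labels, genes, priors = c(high = 0.5, low = 0.5),
                     cutoffs = c(low = 0.3, high = 0.7)) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  labels <- .align_sample_vector(labels, colnames(x$values), "labels")
  if (!all(labels %in% c("high", "low")))
    stop("labels must be 'high' or 'low'")
  if (length(unique(labels)) < 2) stop("single-class training input")
  if (min(table(labels)) < 2) stop("both classes need >= 2 samples")
  if (abs(sum(priors) - 1) > 1e-8 || any(priors <= 0))
    stop("priors must be positive and sum to 1")
  if (!(cutoffs["low"] > 0 && cutoffs["low"] <= cutoffs["high"] &&
        cutoffs["high"] < 1))
    stop("cutoffs must satisfy 0 < low <= high < 1")
  genes <- .resolve_genes(genes)
  hit <- match(toupper(genes), toupper(rownames(x$values)))
  if (all(is.na(hit))) stop("no signature gene found in training matrix")
  if (anyNA(hit))
    message(sprintf("bccp_fit: dropped %d signature gene(s) absent from training",
                    sum(is.na(hit))))
  rows <- hit[!is.na(hit)]
  v <- x$values[rows, , drop = FALSE]
  center <- rowMeans(v)
  scale <- sqrt(.row_vars(v))
  ok <- scale > 0
  if (!all(ok)) {
    message(sprintf("bccp_fit: dropped %d zero-variance gene(s)", sum(!ok)))
    v <- v[ok, , drop = FALSE]; center <- center[ok]; scale <- scale[ok]
  }
  if (nrow(v) == 0) stop("no usable signature gene")
  xs <- (v - center) / scale
  hi <- names(labels)[labels == "high"]
  lo <- names(labels)[labels == "low"]
  w <- .pooled_t(xs, hi, lo)
  w[!is.finite(w)] <- 0
  cc <- colSums(w * xs)
  m_high <- mean(cc[hi]); m_low <- mean(cc[lo])
  s2 <- (sum((cc[hi] - m_high)^2) + sum((cc[lo] - m_low)^2)) /
    (length(cc) - 2)
  if (!is.finite(s2) || s2 <= 0)
    stop("zero within-class variance of the compound covariate")
  structure(list(genes = rownames(v), weights = w, center = center,
                 scale = scale, m_high = m_high, m_low = m_low, s2 = s2,
                 priors = priors, cutoffs = cutoffs,
                 n_high = length(hi), n_low = length(lo),
                 training_covariate = cc),
            class = "BCCPModel")
}

#' @export
print.BCCPModel <- function(x, ...) {
  cat(sprintf(paste0("BCCPModel: %d genes; m_high = %.3f, m_low = %.3f, ",
                     "s2 = %.3f; priors %.2f/%.2f; cutoffs %.2f/%.2f\n"),
              length(x$genes), x$m_high, x$m_low, x$s2,
              x$priors["high"], x$priors["low"],
              x$cutoffs["low"], x$cutoffs["high"]))
  invisible(x)
}

#' Posterior probability of the high class given a compound covariate
#'
#' P(high | c) = pi_h N(c; m_high, s2) / (pi_h N(c; m_high, s2) +
#' pi_l N(c; m_low, s2)), computed in log space for stability.
#'
#' @param model a `BCCPModel`
#' @param cc numeric vector of compound-covariate values
#' @return vector of posterior probabilities in (0, 1)
#' @export
bccp_posterior <- function(model, cc) {
  stopifnot(inherits(model, "BCCPModel"))
  s <- sqrt(model$s2)
  lh <- stats::dnorm(cc, model$m_high, s, log = TRUE) +
    log(model$priors[["high"]])
  ll <- stats::dnorm(cc, model$m_low, s, log = TRUE) +
    log(model$priors[["low"]])
  1 / (1 + exp(ll - lh))
}

#' Compound covariate of new samples
#'
#' Matches the model's genes in the matrix (case-insensitive). With
#' `standardize = "internal"` (the cross-platform default) each gene is
#' z-scored with the matrix's own mean/sd; `"model"` reuses the training
#' constants (appropriate within one platform, e.g. LOOCV folds).
#'
#' @param model a `BCCPModel`
#' @param x an `ExpressionMatrix` of new samples
#' @param standardize `"internal"` or `"model"`
#' @param min_matched minimum fraction of model genes that must match
#' @return named numeric vector, one covariate per sample
#' @export
bccp_covariate <- function(model, x, standardize = c("internal", "model"),
                           min_matched = 0.5) {
  stopifnot(inherits(model, "BCCPModel"), inherits(x, "ExpressionMatrix"))
  standardize <- match.arg(standardize)
  hit <- match(toupper(model$genes), toupper(rownames(x$values)))
  frac <- mean(!is.na(hit))
  if (frac <= min_matched)
    stop(sprintf("only %.0f%% of model genes matched (need > %.0f%%); platform mismatch?",
                 100 * frac, 100 * min_matched))
  keep <- !is.na(hit)
  v <- x$values[hit[keep], , drop = FALSE]
  if (standardize == "internal") {
    center <- rowMeans(v)
    scale <- sqrt(.row_vars(v))
    scale[scale == 0] <- 1
  } else {
    center <- model$center[keep]
    scale <- model$scale[keep]
  }
  colSums(model$weights[keep] * (v - center) / scale)
}

#' Classify a cohort with tri-state calls
#'
#' Labels: `high` if the posterior exceeds the high cutoff, `low` if
#' below the low cutoff, otherwise `undetermined` (excluded from
#' downstream contingency analysis). Cohort genes are standardized
#' within the cohort itself, the minimal cross-platform calibration.
#'
#' @param model a `BCCPModel`
#' @param x cohort `ExpressionMatrix`
#' @param cutoffs posterior cutoffs; defaults to the model's
#' @param standardize see [bccp_covariate()]
#' @return data frame of class `ClassifiedCohort`: `sample`, `cc`,
#'   `p_high`, `label`
#' @export
bccp_classify <- function(model, x, cutoffs = model$cutoffs,
                          standardize = "internal") {
  cc <- bccp_covariate(model, x, standardize = standardize)
  p <- bccp_posterior(model, cc)
  label <- ifelse(p > cutoffs[["high"]], "high",
                  ifelse(p < cutoffs[["low"]], "low", "undetermined"))
  structure(data.frame(sample = names(cc), cc = unname(cc),
                       p_high = unname(p), label = unname(label),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ClassifiedCohort", "data.frame"),
            cutoffs = cutoffs)
}

#' Leave-one-out cross-validated misclassification rate
#'
#' For every held-out sample the entire model — weights, standardization
#' constants and class densities — is re-derived from the remaining
#' samples (no information leak), the held-out covariate is computed with
#' the fold's training constants, and the call is high when P > 0.5.
#' Folds that would lose a whole class are skipped and reported.
#'
#' @inheritParams bccp_fit
#' @return list of class `LoocvResult`: `rate`, `calls` (data frame with
#'   per-sample posterior, call, truth), `n_skipped`
#' @export
bccp_loocv <- function(x, labels, genes, priors = c(high = 0.5, low = 0.5)) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  labels <- .align_sample_vector(labels, colnames(x$values), "labels")
  samples <- colnames(x$values)
  calls <- data.frame(sample = samples, p_high = NA_real_,
                      call = NA_character_, truth = unname(labels),
                      stringsAsFactors = FALSE)
  n_skipped <- 0L
  for (i in seq_along(samples)) {
    train_idx <- setdiff(seq_along(samples), i)
    train_labels <- labels[train_idx]
    if (length(unique(train_labels)) < 2 || min(table(train_labels)) < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    xt <- expression_matrix(x$values[, train_idx, drop = FALSE],
                            x$condition[train_idx],
                            x$replicate[train_idx])
    fold <- bccp_fit(xt, train_labels, genes, priors = priors)
    held <- x$values[, i, drop = FALSE]
    hit <- match(toupper(fold$genes), toupper(rownames(held)))
    cc <- sum(fold$weights * (held[hit, 1] - fold$center) / fold$scale)
    p <- bccp_posterior(fold, cc)
    calls$p_high[i] <- p
    calls$call[i] <- if (p > 0.5) "high" else "low"
  }
  done <- !is.na(calls$call)
  rate <- mean(calls$call[done] != calls$truth[done])
  structure(list(rate = rate, calls = calls, n_skipped = n_skipped),
            class = "LoocvResult")
}

#' @export
print.LoocvResult <- function(x, ...) {
  cat(sprintf("LOOCV: misclassification rate %.3f over %d samples",
              x$rate, sum(!is.na(x$calls$call))))
  if (x$n_skipped > 0) cat(sprintf(" (%d fold(s) skipped)", x$n_skipped))
  cat("\n")
  invisible(x)
}

#' Serialize a BCCP model to JSON
#' @param model a `BCCPModel`
#' @param path output path
#' @export
bccp_to_json <- function(model, path) {
  stopifnot(inherits(model, "BCCPModel"))
  out <- list(genes = model$genes, weights = unname(model$weights),
              center = unname(model$center), scale = unname(model$scale),
              m_high = model$m_high, m_low = model$m_low, s2 = model$s2,
              priors = as.list(model$priors),
              cutoffs = as.list(model$cutoffs),
              n_high = model$n_high, n_low = model$n_low)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a BCCP model from JSON
#' @param path path written by [bccp_to_json()]
#' @return a `BCCPModel`
#' @export
bccp_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(genes = j$genes,
                 weights = stats::setNames(j$weights, j$genes),
                 center = stats::setNames(j$center, j$genes),
                 scale = stats::setNames(j$scale, j$genes),
                 m_high = j$m_high, m_low = j$m_low, s2 = j$s2,
                 priors = unlist(j$priors), cutoffs = unlist(j$cutoffs),
                 n_high = j$n_high, n_low = j$n_low),
            class = "BCCPModel")
}
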