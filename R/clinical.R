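# Survival stratification and predictive-value statistics: Kaplan-Meier
# product-limit curves, the two-group log-rank test, chi-square
# contingency tests of chemo response, and ROC/AUC with a seeded
# stratified percentile bootstrap. Events are processed before
# censorings at tied times (the standard convention).

.check_surv <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be non-negative and finite")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; censored subjects leave the risk set after
#' their time. A thin wrapper around [survival::survfit()] that returns
#' the curve as a plain table.
#'
#' @param times follow-up times (months)
#' @param events 0/1 event indicators (1 = event)
#' @return data frame of class `SurvivalCurve`: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`
#' @export
km_estimate <- function(times, events) {
  .check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv, row.names = NULL),
            class = c("SurvivalCurve", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic under pooled risk sets
#' with hypergeometric variance, referred to chi-square with 1 df. A
#' wrapper around [survival::survdiff()].
#'
#' @param times_a,events_a group A follow-up and 0/1 events
#' @param times_b,events_b group B follow-up and 0/1 events
#' @return list with `chi_square` and `p`
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  .check_surv(times_a, events_a)
  .check_surv(times_b, events_b)
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events in either group")
  df <- data.frame(time = c(times_a, times_b),
                   event = c(events_a, events_b),
                   group = rep(c("A", "B"),
                               c(length(times_a), length(times_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(chi_square = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Pearson chi-square test of a 2x2 contingency table
#'
#' No continuity correction by default (switchable), so the statistic is
#' n(ad - bc)^2 / (r1 r2 c1 c2). Per-row proportions are reported so
#' statements like "15 of 18" are reproducible from a supplied table.
#'
#' @param counts 2x2 matrix of non-negative integer counts
#' @param correct apply the Yates continuity correction
#' @return list of class `ContingencyResult`: `counts`, `chi_square`,
#'   `p`, `row_proportions`
#' @export
contingency_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("need a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin; consider an exact test")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(counts = counts,
                 chi_square = unname(ct$statistic),
                 p = ct$p.value,
                 row_proportions = counts / rowSums(counts)),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("ContingencyResult: chi-square = %.3f, p = %.3g\n",
              x$chi_square, x$p))
  print(x$counts)
  invisible(x)
}

# Rank-based AUC: the Mann-Whitney statistic normalized by n+ * n-,
# with ties counted one half via midranks.
.auc <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC AUC with a seeded stratified bootstrap confidence interval
#'
#' The AUC is the rank-based concordance probability (Mann-Whitney
#' statistic normalized by the number of positive-negative pairs, ties
#' counted one half). The confidence interval is a percentile interval
#' over bootstrap resamples stratified by class.
#'
#' @param scores numeric predictor (e.g. the BCCP posterior, oriented so
#'   higher predicts the positive label)
#' @param labels 0/1 (or logical) outcome labels; both classes required
#' @param n_boot bootstrap resamples (default 2000)
#' @param seed integer seed for the bootstrap
#' @param conf confidence level of the percentile interval
#' @return list of class `ROCResult`: `auc`, `ci_lower`, `ci_upper`,
#'   `n_boot`, `seed`, `n_pos`, `n_neg`
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1,
                    conf = 0.95) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2)
    stop("both label classes must be present")
  auc <- .auc(scores, labels)
  ipos <- which(labels == 1); ineg <- which(labels == 0)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(ipos[sample.int(length(ipos), replace = TRUE)],
               ineg[sample.int(length(ineg), replace = TRUE)])
      .auc(scores[idx], labels[idx])
    }, 1)
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  structure(list(auc = auc, ci_lower = ci[1], ci_upper = ci[2],
                 n_boot = n_boot, seed = seed, conf = conf,
                 n_pos = length(ipos), n_neg = length(ineg)),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROCResult: AUC = %.4f (%.0f%% CI %.4f-%.4f, %d resamples)\n",
              x$auc, 100 * x$conf, x$ci_lower, x$ci_upper, x$n_boot))
  invisible(x)
}
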