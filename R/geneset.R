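# Parametric (PAGE-style) gene-set activity Z-scores over a contrast's
# fold changes, plus the rank-distribution and cross-condition analyses
# built on them. For a MIR (miRNA-target) collection a positive Z means
# target genes are collectively elevated, i.e. the corresponding miRNA's
# activity is low.

#' Activity Z-score of one gene set
#'
#' z = (S_m - mu) * sqrt(m) / sigma, where S_m is the mean log2 fold
#' change of the m set members matched in the contrast (case-insensitive
#' symbol match), mu the mean fold change of all genes, and sigma the
#' standard deviation of all fold changes. Under a null contrast with
#' randomly sampled members, z is approximately standard normal.
#'
#' @param ct a `ContrastResult`
#' @param members character vector of member gene symbols
#' @param min_set_size minimum matched members (default 5; the sqrt(m)
#'   scaling is unstable below that)
#' @return list with `z` and effective member count `m`
#' @export
set_zscore <- function(ct, members, min_set_size = 5) {
  stopifnot(inherits(ct, "ContrastResult"))
  idx <- which(toupper(ct$gene) %in% unique(toupper(members)))
  m <- length(idx)
  if (m < min_set_size)
    stop("only ", m, " member gene(s) matched; below min_set_size = ",
         min_set_size)
  sigma <- stats::sd(ct$fc)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate contrast: zero fold-change standard deviation")
  z <- (mean(ct$fc[idx]) - mean(ct$fc)) * sqrt(m) / sigma
  list(z = z, m = m)
}

#' Activity Z-scores for every set of a collection
#'
#' Sets with fewer than `min_set_size` matched members are skipped (with
#' a message); an error is raised if no set is admissible.
#'
#' @param ct a `ContrastResult`
#' @param collection a `GeneSetCollection`
#' @param min_set_size minimum matched members per set
#' @return data frame of class `SetActivityProfile` with columns `set`,
#'   `m`, `z` and attributes `contrast_name`, `collection_name`
#' @export
profile_collection <- function(ct, collection, min_set_size = 5) {
  stopifnot(inherits(ct, "ContrastResult"),
            inherits(collection, "GeneSetCollection"))
  if (length(collection$sets) == 0)
    stop("refusing to profile an empty collection")
  genes_up <- toupper(ct$gene)
  sigma <- stats::sd(ct$fc)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate contrast: zero fold-change standard deviation")
  mu <- mean(ct$fc)
  ms <- vapply(collection$sets,
               function(g) sum(genes_up %in% g), 1L)
  admissible <- ms >= min_set_size
  if (!any(admissible))
    stop("no set has >= ", min_set_size, " matched members")
  if (any(!admissible))
    message(sprintf("profile_collection: skipped %d of %d sets below %d members",
                    sum(!admissible), length(ms), min_set_size))
  zs <- vapply(collection$sets[admissible], function(g) {
    idx <- genes_up %in% g
    (mean(ct$fc[idx]) - mu) * sqrt(sum(idx)) / sigma
  }, 1)
  res <- data.frame(set = names(zs), m = ms[admissible], z = unname(zs),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("SetActivityProfile", "data.frame"),
            contrast_name = attr(ct, "contrast_name"),
            collection_name = collection$name,
            min_set_size = min_set_size)
}

#' Sorted rank distribution of a set-activity profile
#'
#' Z-scores sorted ascending (ties broken by set name); counts of
#' depleted (z < 0), enriched (z > 0) and exactly-zero sets; and the
#' x-intercept rank, the 1-based rank of the first non-negative score.
#'
#' @param profile a `SetActivityProfile`
#' @return list of class `RankDistribution`
#' @export
rank_distribution <- function(profile) {
  stopifnot(inherits(profile, "SetActivityProfile"))
  if (nrow(profile) == 0) stop("empty profile")
  o <- order(profile$z, profile$set)
  z <- stats::setNames(profile$z[o], profile$set[o])
  structure(list(z = z,
                 n_depleted = sum(z < 0),
                 n_enriched = sum(z > 0),
                 n_zero = sum(z == 0),
                 x_intercept_rank = sum(z < 0) + 1L),
            class = "RankDistribution")
}

#' @export
print.RankDistribution <- function(x, ...) {
  cat(sprintf(paste0("RankDistribution: %d sets (%d depleted, %d enriched",
                     ", %d zero), x-intercept at rank %d\n"),
              length(x$z), x$n_depleted, x$n_enriched, x$n_zero,
              x$x_intercept_rank))
  invisible(x)
}

#' Compare two set-activity profiles of the same collection
#'
#' Pearson correlation of paired Z-scores (matched by set name), the
#' regression F-statistic p-value, and quadrant counts of the sign pairs
#' (Q1: both positive, Q2: A negative/B positive, Q3: both negative,
#' Q4: A positive/B negative; sets with a zero score fall in no quadrant).
#'
#' @param pa,pb `SetActivityProfile`s over the same collection
#' @return list of class `ProfileComparison`: `n_sets`, `pearson_r`,
#'   `p_value`, `quadrants`
#' @export
compare_profiles <- function(pa, pb) {
  stopifnot(inherits(pa, "SetActivityProfile"),
            inherits(pb, "SetActivityProfile"))
  m <- merge(pa[, c("set", "z")], pb[, c("set", "z")], by = "set",
             suffixes = c("_a", "_b"))
  if (nrow(m) < 3) stop("fewer than 3 shared sets")
  pf <- .pearson_f(m$z_a, m$z_b)
  quadrants <- c(Q1 = sum(m$z_a > 0 & m$z_b > 0),
                 Q2 = sum(m$z_a < 0 & m$z_b > 0),
                 Q3 = sum(m$z_a < 0 & m$z_b < 0),
                 Q4 = sum(m$z_a > 0 & m$z_b < 0))
  structure(list(n_sets = nrow(m), pearson_r = pf$r, p_value = pf$p,
                 quadrants = quadrants),
            class = "ProfileComparison")
}

#' @export
print.ProfileComparison <- function(x, ...) {
  cat(sprintf("ProfileComparison: %d sets, Pearson r = %.4f, p = %.3g\n",
              x$n_sets, x$pearson_r, x$p_value))
  print(x$quadrants)
  invisible(x)
}

#' Rank sets by a sum of oriented Z-scores across profiles
#'
#' Per set, score = sum over profiles of orientation_k * z_k, where the
#' orientation (+1 or -1) points every profile toward the nc886-high
#' direction (a knockdown contrast gets -1). Sets missing from any
#' profile are excluded with a message. Ordered by descending score,
#' ties broken by set name.
#'
#' @param profiles list of `SetActivityProfile`s over one collection
#' @param orientations numeric vector of +1/-1, one per profile
#' @return data frame with columns `set`, `score`, `rank`
#' @export
rank_mirs <- function(profiles, orientations = rep(1, length(profiles))) {
  if (length(profiles) == 0) stop("no profiles supplied")
  if (length(orientations) != length(profiles))
    stop("need one orientation per profile")
  if (!all(orientations %in% c(-1, 1)))
    stop("orientations must be +1 or -1")
  colls <- vapply(profiles, attr, "", "collection_name")
  if (length(unique(colls)) != 1)
    stop("profiles must share one collection")
  shared <- Reduce(intersect, lapply(profiles, `[[`, "set"))
  n_all <- length(unique(unlist(lapply(profiles, `[[`, "set"))))
  if (length(shared) < n_all)
    message(sprintf("rank_mirs: excluded %d set(s) missing from >=1 profile",
                    n_all - length(shared)))
  if (length(shared) == 0) stop("no set shared by all profiles")
  score <- numeric(length(shared))
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    score <- score + orientations[k] *
      p$z[match(shared, p$set)]
  }
  o <- order(-score, shared)
  data.frame(set = shared[o], score = score[o],
             rank = seq_along(shared), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a set-activity profile as CSV
#' @param profile a `SetActivityProfile`
#' @param path output path
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  df$collection <- attr(profile, "collection_name")
  df$rank <- rank(df$z, ties.method = "first")
  utils::write.csv(df[, c("collection", "set", "m", "z", "rank")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
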