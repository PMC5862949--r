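# Synthetic data with planted ground truth. All randomness in a generator
# call flows from the design's single seed; the caller's RNG state is
# saved and restored so generation never perturbs an enclosing simulation.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Design of a planted two-or-more-condition expression experiment
#'
#' Describes a triplicated array experiment: per-gene Gaussian baselines
#' on the log2 scale, homoscedastic Gaussian noise, and additive log2
#' shifts planted on the member genes of chosen sets in chosen conditions.
#' Defaults mirror a typical array: baselines N(8, 2), noise sd 0.5,
#' triplicates.
#'
#' @param conditions character vector of condition labels
#' @param nc886_level named character, `"high"` or `"low"` per condition;
#'   used downstream to orient contrasts toward nc886-high
#' @param collection `GeneSetCollection` the planted sets are drawn from
#' @param planted named list: condition -> `list(sets = <names>, delta =
#'   <log2 shift>)`; every named set must exist in `collection`
#' @param replicates replicates per condition (>= 2)
#' @param n_genes number of genes; gene ids are `G00001`, ... and include
#'   all collection members
#' @param noise_sd per-sample Gaussian noise sd, log2 units
#' @param baseline_mean,baseline_sd per-gene baseline distribution
#' @param seed integer seed driving all randomness of the experiment
#' @return a validated list of class `ExperimentDesign`
#' @export
experiment_design <- function(conditions, nc886_level, collection,
                              planted = list(), replicates = 3,
                              n_genes = 10000, noise_sd = 0.5,
                              baseline_mean = 8, baseline_sd = 2,
                              seed = 1) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (replicates < 2) stop("'replicates' must be >= 2")
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  nc886_level <- nc886_level[conditions]
  if (anyNA(nc886_level) || !all(nc886_level %in% c("high", "low")))
    stop("'nc886_level' must map every condition to 'high' or 'low'")
  for (cond in names(planted)) {
    if (!cond %in% conditions)
      stop("planted condition '", cond, "' not in design")
    p <- planted[[cond]]
    absent <- setdiff(p$sets, names(collection$sets))
    if (length(absent) > 0)
      stop("planted set(s) absent from collection: ",
           paste(absent, collapse = ", "))
    if (!is.finite(p$delta)) stop("planted delta must be finite")
  }
  members <- unique(unlist(collection$sets, use.names = FALSE))
  if (n_genes < length(members))
    stop("'n_genes' smaller than the collection's gene universe")
  structure(list(conditions = conditions, nc886_level = nc886_level,
                 collection = collection, planted = planted,
                 replicates = replicates, n_genes = n_genes,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = seed),
            class = "ExperimentDesign")
}

#' Generate a planted expression experiment
#'
#' Per gene g a baseline b_g ~ N(baseline_mean, baseline_sd) is drawn; a
#' sample in condition c has value b_g + delta_c * 1[g in a planted set of
#' c] + N(0, noise_sd). The returned truth record lists the planted sets,
#' their member genes, and the shifts, sufficient to score recovery.
#'
#' @param design an [experiment_design()]
#' @return list with elements `matrix` (an `ExpressionMatrix`) and `truth`
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "ExperimentDesign"))
  .with_seed(design$seed, {
    members <- unique(unlist(design$collection$sets, use.names = FALSE))
    # collection members occupy the first rows so set matching is exact;
    # filler symbols are drawn around them to avoid collisions
    filler <- setdiff(sprintf("G%05d",
                              seq_len(design$n_genes + length(members))),
                      members)
    genes <- c(members,
               filler[seq_len(design$n_genes - length(members))])
    baseline <- stats::rnorm(design$n_genes, design$baseline_mean,
                             design$baseline_sd)
    names(baseline) <- genes
    cols <- list()
    cond_vec <- character(0)
    for (cond in design$conditions) {
      shift <- numeric(design$n_genes)
      names(shift) <- genes
      p <- design$planted[[cond]]
      if (!is.null(p)) {
        pg <- unique(unlist(design$collection$sets[p$sets],
                            use.names = FALSE))
        shift[pg] <- p$delta
      }
      for (r in seq_len(design$replicates)) {
        smp <- paste(cond, r, sep = "_")
        cols[[smp]] <- baseline + shift +
          stats::rnorm(design$n_genes, 0, design$noise_sd)
        cond_vec[smp] <- cond
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    truth <- list(
      planted = lapply(design$planted, function(p) {
        list(sets = p$sets, delta = p$delta,
             genes = unique(unlist(design$collection$sets[p$sets],
                                   use.names = FALSE)))
      }),
      nc886_level = design$nc886_level,
      noise_sd = design$noise_sd, seed = design$seed)
    list(matrix = expression_matrix(values, cond_vec), truth = truth)
  })
}

#' Simulate a random gene-set collection
#'
#' Draws `n_sets` sets of `set_size` symbols each from a universe of
#' `n_genes` symbols (sampling without replacement within a set; sets may
#' overlap), emulating an MSigDB-style collection for simulation studies.
#'
#' @param n_sets,set_size collection shape
#' @param n_genes universe size; symbols are `G00001`...
#' @param name collection label, also the set-name prefix
#' @param seed integer seed
#' @return a [gene_set_collection()]
#' @export
random_collection <- function(n_sets = 200, set_size = 50, n_genes = 10000,
                              name = "MIR", seed = 1) {
  .with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    sets <- lapply(seq_len(n_sets), function(i) sample(genes, set_size))
    names(sets) <- sprintf("%s_SET_%03d", name, seq_len(n_sets))
    gene_set_collection(sets, name)
  })
}

#' Design of a synthetic patient cohort
#'
#' Emulates an expression-profiled ovarian-cancer cohort: a latent
#' nc886-high/low subtype per patient drives signature-gene expression,
#' an exponential survival hazard, and the chemo-resistance probability.
#' Censoring is independent exponential, tuned to the requested rate.
#'
#' @param n_patients cohort size (default 285, a typical array cohort)
#' @param prevalence probability a patient is nc886-high
#' @param signature_genes symbols shifted in nc886-high patients
#' @param signature_signs optional +1/-1 direction per signature gene
#'   (default all +1), so down-in-high signature blocks can be emulated
#' @param delta_sig absolute log2 shift of signature genes in high
#'   patients
#' @param n_background unshifted background genes added to the matrix
#' @param noise_sd,baseline_mean,baseline_sd as in [experiment_design()]
#' @param baseline_hazard overall-survival events per month for the low
#'   subtype (default 0.015, median survival near 4 years)
#' @param hazard_ratio high-vs-low hazard ratio (> 0)
#' @param censoring_rate target fraction censored (0 disables censoring)
#' @param rfs_multiplier recurrence hazard relative to death hazard
#' @param p_resistant_high,p_resistant_low chemo-resistance probability
#'   per subtype
#' @param seed integer seed
#' @return a validated list of class `CohortDesign`
#' @export
cohort_design <- function(n_patients = 285, prevalence = 0.5,
                          signature_genes = sprintf("SIG%03d", 1:118),
                          signature_signs = rep(1, length(signature_genes)),
                          delta_sig = 1, n_background = 500,
                          noise_sd = 0.5, baseline_mean = 8,
                          baseline_sd = 2, baseline_hazard = 0.015,
                          hazard_ratio = 3, censoring_rate = 0.3,
                          rfs_multiplier = 2, p_resistant_high = 0.15,
                          p_resistant_low = 0.02, seed = 1) {
  probs <- c(prevalence, censoring_rate, p_resistant_high, p_resistant_low)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (hazard_ratio <= 0) stop("'hazard_ratio' must be > 0")
  if (baseline_hazard <= 0) stop("'baseline_hazard' must be > 0")
  if (length(signature_signs) != length(signature_genes) ||
      !all(signature_signs %in% c(-1, 1)))
    stop("'signature_signs' must be +1/-1, one per signature gene")
  structure(as.list(environment()), class = "CohortDesign")
}

#' Generate a synthetic patient cohort
#'
#' @param design a [cohort_design()]
#' @return list with `matrix` (`ExpressionMatrix`), `clinical`
#'   (`ClinicalTable`) and `truth` (latent subtype per patient plus the
#'   design parameters)
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  .with_seed(design$seed, {
    n <- design$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    high <- stats::rbinom(n, 1, design$prevalence) == 1
    genes <- c(design$signature_genes,
               sprintf("BG%05d", seq_len(design$n_background)))
    baseline <- stats::rnorm(length(genes), design$baseline_mean,
                             design$baseline_sd)
    values <- baseline +
      matrix(stats::rnorm(length(genes) * n, 0, design$noise_sd),
             nrow = length(genes))
    sig_rows <- seq_along(design$signature_genes)
    values[sig_rows, high] <- values[sig_rows, high] +
      design$delta_sig * design$signature_signs
    dimnames(values) <- list(genes, ids)

    hazard <- design$baseline_hazard *
      ifelse(high, design$hazard_ratio, 1)
    os_t <- stats::rexp(n, hazard)
    rfs_t <- stats::rexp(n, hazard * design$rfs_multiplier)
    if (design$censoring_rate > 0) {
      mean_h <- design$baseline_hazard *
        (design$prevalence * design$hazard_ratio + 1 - design$prevalence)
      cens_rate <- design$censoring_rate / (1 - design$censoring_rate) *
        mean_h
      cens <- stats::rexp(n, cens_rate)
    } else {
      cens <- rep(Inf, n)
    }
    clin <- clinical_table(data.frame(
      patient_id = ids,
      os_time = pmin(os_t, cens),
      os_event = as.integer(os_t <= cens),
      rfs_time = pmin(rfs_t, cens),
      rfs_event = as.integer(rfs_t <= cens),
      chemo_response = ifelse(
        stats::rbinom(n, 1, ifelse(high, design$p_resistant_high,
                                   design$p_resistant_low)) == 1,
        "resistant", "sensitive"),
      stringsAsFactors = FALSE))
    truth <- list(subtype = stats::setNames(ifelse(high, "high", "low"),
                                            ids),
                  signature_genes = design$signature_genes,
                  delta_sig = design$delta_sig,
                  hazard_ratio = design$hazard_ratio,
                  seed = design$seed)
    mat <- expression_matrix(values,
                             stats::setNames(rep("patient", n), ids))
    list(matrix = mat, clinical = clin, truth = truth)
  })
}

#' Write a truth record as JSON
#' @param truth a truth record from a generator
#' @param path output path
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
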