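# Builders for small in-code fixtures and independent brute-force
# oracles used across the suite.

fake_contrast <- function(genes, fc, p = rep(0.01, length(genes)),
                          degenerate = rep(FALSE, length(genes)),
                          name = "fake") {
  structure(data.frame(gene = genes, fc = fc,
                       t = rep(NA_real_, length(genes)), p = p,
                       degenerate = degenerate,
                       stringsAsFactors = FALSE),
            class = c("ContrastResult", "data.frame"),
            contrast_name = name, n_treatment = 3, n_reference = 3,
            df = 4)
}

fake_profile <- function(sets, z, collection = "MIR", name = "fake") {
  structure(data.frame(set = sets, m = 50L, z = z,
                       stringsAsFactors = FALSE),
            class = c("SetActivityProfile", "data.frame"),
            contrast_name = name, collection_name = collection,
            min_set_size = 5)
}

# labelled two-class matrix with `delta` added to every gene in "high"
make_labeled_matrix <- function(n_genes = 50, n_per = 6, delta = 1.5,
                                noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- c(paste0("L", seq_len(n_per)), paste0("H", seq_len(n_per)))
  v <- matrix(rnorm(n_genes * 2 * n_per, 8, noise_sd), n_genes,
              dimnames = list(genes, samples))
  v[, seq_len(n_per) + n_per] <- v[, seq_len(n_per) + n_per] + delta
  labels <- setNames(rep(c("low", "high"), each = n_per), samples)
  list(x = expression_matrix(v, labels), labels = labels)
}

# a panel of two-condition triplicated experiments with the same MIR
# sets planted toward nc886-high (the last experiment is a knockdown,
# planted negatively, orientation -1)
sim_mir_panel <- function(seed, n_sets = 200, set_size = 50,
                          n_genes = 10000, n_planted = 5, delta = 0.5,
                          noise_sd = 0.5, n_experiments = 4,
                          with_tft = FALSE) {
  mir <- random_collection(n_sets, set_size, n_genes, name = "MIR",
                           seed = seed * 1000 + 1)
  tft <- if (with_tft)
    random_collection(n_sets, set_size, n_genes, name = "TFT",
                      seed = seed * 1000 + 2)
  planted <- names(mir$sets)[seq_len(n_planted)]
  orientations <- if (n_experiments == 1) 1 else
    c(rep(1, n_experiments - 1), -1)
  experiments <- lapply(seq_len(n_experiments), function(k) {
    d <- delta * orientations[k]
    generate_experiment(experiment_design(
      conditions = c("control", "treated"),
      nc886_level = c(control = "low", treated = "high"),
      collection = mir,
      planted = list(treated = list(sets = planted, delta = d)),
      n_genes = n_genes, noise_sd = noise_sd,
      seed = seed * 1000 + 10 + k))
  })
  contrasts <- lapply(experiments, function(e)
    contrast(e$matrix, "treated", "control"))
  profiles <- lapply(contrasts, function(ct)
    suppressMessages(profile_collection(ct, mir)))
  tft_profiles <- if (with_tft) lapply(contrasts, function(ct)
    suppressMessages(profile_collection(ct, tft)))
  list(mir = mir, tft = tft, planted = planted, contrasts = contrasts,
       profiles = profiles, tft_profiles = tft_profiles,
       orientations = orientations)
}

# exhaustive concordance-count AUC (ties count one half)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# naive O(n^3) average-linkage agglomeration; returns the cophenetic
# distance matrix for comparison against hclust
naive_average_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- NULL; bd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bd) { bd <- dd; best <- c(j, i) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bd; coph[b, a] <- bd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

write_tsv_fixture <- function(lines, path) {
  writeLines(lines, path)
  path
}
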