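test_that("divergent genes are exactly those passing the median-deviation rule", {
  # 4 genes x 3 experiments (2 samples each); deviations known by design
  v <- rbind(
    flat  = rep(5, 6),
    up1   = c(6, 6, 5, 5, 5, 5),        # deviation exactly 1 in e1
    up2   = c(6.2, 6.2, 6.2, 6.2, 5, 5),
    small = c(5.2, 5.2, 5, 5, 5, 5))
  colnames(v) <- paste0("s", 1:6)
  x <- expression_matrix(v, rep(c("e1", "e2", "e3"), each = 2))
  exps <- split(colnames(v), rep(c("e1", "e2", "e3"), each = 2))

  # deviation exactly log2(threshold): inclusive rule selects it
  boundary <- suppressMessages(divergent_genes(x, exps, 2, 1))
  expect_true("up1" %in% boundary)
  expect_false("flat" %in% boundary)  # constant gene never selected

  sel <- suppressMessages(divergent_genes(x, exps, 1.5, 1))
  expect_false("flat" %in% sel)
  expect_true("up2" %in% sel)
  expect_false("small" %in% sel)

  # brute-force oracle over all genes/experiments
  med <- apply(v, 1, median)
  brute <- rownames(v)[vapply(rownames(v), function(g) {
    dev <- vapply(exps, function(s) mean(v[g, s]) - med[g], 1)
    sum(abs(dev) >= log2(1.5)) >= 1
  }, TRUE)]
  expect_setequal(sel, brute)

  two <- suppressMessages(divergent_genes(x, exps, 1.5, 2))
  expect_setequal(two, rownames(v)[vapply(rownames(v), function(g) {
    dev <- vapply(exps, function(s) mean(v[g, s]) - med[g], 1)
    sum(abs(dev) >= log2(1.5)) >= 2
  }, TRUE)])
})

test_that("signature selection enforces recurrence and sign consistency", {
  g <- c("consistent", "inconsistent", "weak")
  cts <- lapply(list(c(0.5, 0.5, 0.2), c(0.5, 0.5, 0.2),
                     c(0.5, -0.5, 0.2), c(0.0, 0.0, 0.0)),
                function(fc) fake_contrast(g, fc))
  sig <- suppressMessages(signature_genes(cts, fold_threshold = 1.3,
                                          min_experiments = 3))
  # (0.5, 0.5, 0.5, 0) passes 3 times with one sign -> selected
  expect_true("consistent" %in% sig$gene)
  # (0.5, 0.5, -0.5, 0) passes 3 times but signs disagree -> rejected
  expect_false("inconsistent" %in% sig$gene)
  expect_false("weak" %in% sig$gene)

  loose <- suppressMessages(signature_genes(cts, fold_threshold = 1.3,
                                            min_experiments = 3,
                                            sign_consistent = FALSE))
  expect_true("inconsistent" %in% loose$gene)

  # a knockdown contrast supplied with orientation -1 is negated first
  kd <- fake_contrast(g, c(-0.5, -0.5, -0.2))
  sig2 <- suppressMessages(signature_genes(
    list(cts[[1]], cts[[2]], kd), orientations = c(1, 1, -1),
    min_experiments = 3))
  expect_true("consistent" %in% sig2$gene)
  expect_equal(attr(sig2, "rule")$fold_threshold, 1.3)
})

test_that("signature selection is invariant to gene order", {
  set.seed(5)
  g <- sprintf("g%02d", 1:20)
  fcs <- replicate(4, rnorm(20, 0, 0.5), simplify = FALSE)
  cts <- lapply(fcs, function(fc) fake_contrast(g, fc))
  perm <- sample(20)
  cts_perm <- lapply(fcs, function(fc) fake_contrast(g[perm], fc[perm]))
  s1 <- suppressMessages(signature_genes(cts, min_experiments = 2))
  s2 <- suppressMessages(signature_genes(cts_perm, min_experiments = 2))
  expect_setequal(s1$gene, s2$gene)
})

test_that("planted signature genes are recovered with high precision and recall", {
  coll <- gene_set_collection(list(SIG = sprintf("P%03d", 1:100)), "SIG")
  cts <- lapply(1:4, function(k) {
    e <- generate_experiment(experiment_design(
      conditions = c("ctl", "trt"),
      nc886_level = c(ctl = "low", trt = "high"),
      collection = coll,
      planted = list(trt = list(sets = "SIG", delta = 1)),
      n_genes = 300, noise_sd = 0.5, seed = 4000 + k))
    contrast(e$matrix, "trt", "ctl")
  })
  sig <- suppressMessages(signature_genes(cts, fold_threshold = 1.3,
                                          min_experiments = 3))
  truth <- sprintf("P%03d", 1:100)
  recall <- mean(truth %in% sig$gene)
  precision <- mean(sig$gene %in% truth)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("clustering recovers planted sample groups and orders duplicates first", {
  set.seed(9)
  # 3 vs 4 samples; 40 genes anti-correlated between groups
  v <- matrix(rnorm(40 * 7, 0, 0.3), 40, 7,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:7)))
  v[1:20, 1:3] <- v[1:20, 1:3] + 2
  v[21:40, 4:7] <- v[21:40, 4:7] + 2
  x <- expression_matrix(v, rep(c("low", "high"), c(3, 4)))
  cl <- hierarchical_cluster(x)
  part <- cl$partition
  expect_length(unique(part[1:3]), 1L)
  expect_length(unique(part[4:7]), 1L)
  expect_true(part[1] != part[4])

  # duplicate samples are at distance 0 and merge first
  vd <- cbind(v, s8 = v[, "s7"])
  xd <- expression_matrix(vd, c(rep("low", 3), rep("high", 5)))
  cld <- hierarchical_cluster(xd)
  hc <- cld$sample_hclust
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first_pair <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first_pair, c("s7", "s8"))
})

test_that("clustering agrees with a brute-force agglomeration oracle", {
  set.seed(10)
  for (rep in 1:3) {
    n <- sample(5:8, 1)
    v <- matrix(rnorm(30 * n), 30, n,
                dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:n)))
    x <- expression_matrix(v, rep("c", n))
    cl <- hierarchical_cluster(x)
    d <- as.dist(1 - cor(v - apply(v, 1, median)))
    expect_equal(as.matrix(stats::cophenetic(cl$sample_hclust)),
                 naive_average_cophenetic(d), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("candidate targets require opposed directions and MIR membership", {
  g <- paste0("g", 1:20)
  set.seed(11)
  kd_fc <- rnorm(20); ind_fc <- rnorm(20)
  kd_p <- runif(20, 0, 0.1); ind_p <- runif(20, 0, 0.1)
  kd <- fake_contrast(g, kd_fc, kd_p)
  ind <- fake_contrast(g, ind_fc, ind_p)
  mir <- gene_set_collection(list(M1 = g[1:8], M2 = g[7:12]), "MIR")

  out <- suppressMessages(candidate_targets(kd, ind, mir, p_cut = 0.05))
  # exhaustive filter evaluation as oracle
  brute <- g[kd_p < 0.05 & ind_p < 0.05 & kd_fc < 0 & ind_fc > 0 &
               toupper(g) %in% toupper(g[1:12])]
  expect_setequal(out, brute)

  both_down <- fake_contrast("x", -1, 0.01)
  expect_length(suppressMessages(
    candidate_targets(both_down, both_down, mir)), 0L)
  expect_error(candidate_targets(kd, ind, list()), "empty MIR")
})
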