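test_that("fit reproduces a hand-worked 4-sample, 2-gene example", {
  v <- rbind(g1 = c(1, 2, 5, 6), g2 = c(10, 11, 13, 14))
  colnames(v) <- c("l1", "l2", "h1", "h2")
  labels <- c(l1 = "low", l2 = "low", h1 = "high", h2 = "high")
  x <- expression_matrix(v, labels)
  model <- bccp_fit(x, labels, c("g1", "g2"))

  # independent arithmetic on the same numbers
  xs <- t(apply(v, 1, function(r) (r - mean(r)) / sd(r)))
  tg <- apply(xs, 1, function(r)
    unname(t.test(r[3:4], r[1:2], var.equal = TRUE)$statistic))
  cc <- colSums(tg * xs)
  m_high <- mean(cc[3:4]); m_low <- mean(cc[1:2])
  s2 <- (sum((cc[3:4] - m_high)^2) + sum((cc[1:2] - m_low)^2)) / 2
  expect_equal(unname(model$weights), unname(tg), tolerance = 1e-12)
  expect_equal(unname(model$training_covariate), unname(cc),
               tolerance = 1e-12)
  expect_equal(model$m_high, m_high, tolerance = 1e-12)
  expect_equal(model$m_low, m_low, tolerance = 1e-12)
  expect_equal(model$s2, s2, tolerance = 1e-12)
})

test_that("separated classes put every training posterior on the right side", {
  d <- make_labeled_matrix(n_genes = 30, n_per = 4, delta = 3,
                           noise_sd = 0.5, seed = 21)
  model <- bccp_fit(d$x, d$labels, rownames(d$x$values))
  p <- bccp_posterior(model, model$training_covariate)
  expect_true(all(p[d$labels == "high"] > 0.5))
  expect_true(all(p[d$labels == "low"] < 0.5))
})

test_that("relabelling high/low swaps the class model and flips posteriors", {
  d <- make_labeled_matrix(seed = 22)
  m1 <- bccp_fit(d$x, d$labels, rownames(d$x$values))
  swapped <- ifelse(d$labels == "high", "low", "high")
  names(swapped) <- names(d$labels)
  m2 <- bccp_fit(d$x, swapped, rownames(d$x$values))
  # weights are negated, so the covariate and class means negate
  expect_equal(unname(m2$weights), -unname(m1$weights), tolerance = 1e-12)
  expect_equal(m2$m_high, -m1$m_low, tolerance = 1e-12)
  cc <- seq(-5, 5, length.out = 11)
  expect_equal(bccp_posterior(m2, -cc), 1 - bccp_posterior(m1, cc),
               tolerance = 1e-12)
})

test_that("posterior equals the two-Gaussian logistic closed form", {
  model <- structure(list(m_high = 1, m_low = -1, s2 = 1,
                          priors = c(high = 0.5, low = 0.5)),
                     class = "BCCPModel")
  expect_equal(bccp_posterior(model, 0), 0.5)
  expect_equal(bccp_posterior(model, 1), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(bccp_posterior(model, 1), 0.8808, tolerance = 1e-4)

  set.seed(23)
  for (i in 1:200) {
    mh <- rnorm(1); ml <- rnorm(1); s2 <- runif(1, 0.1, 4)
    ph <- runif(1, 0.05, 0.95)
    m <- structure(list(m_high = mh, m_low = ml, s2 = s2,
                        priors = c(high = ph, low = 1 - ph)),
                   class = "BCCPModel")
    cc <- rnorm(5, 0, 3)
    closed <- 1 / (1 + (1 - ph) / ph *
                     exp(-(mh - ml) * (cc - (mh + ml) / 2) / s2))
    expect_equal(bccp_posterior(m, cc), closed, tolerance = 1e-12)
  }

  # strictly increasing in the covariate when m_high > m_low
  cc <- seq(-10, 10, length.out = 101)
  expect_true(all(diff(bccp_posterior(model, cc)) > 0))
})

test_that("LOOCV re-derives the model per fold and is deterministic", {
  d <- make_labeled_matrix(n_genes = 50, n_per = 6, delta = 1.5,
                           noise_sd = 0.5, seed = 24)
  cv1 <- suppressMessages(bccp_loocv(d$x, d$labels, rownames(d$x$values)))
  cv2 <- suppressMessages(bccp_loocv(d$x, d$labels, rownames(d$x$values)))
  expect_identical(cv1$rate, cv2$rate)
  expect_equal(cv1$rate, 0)  # class shift 3x noise sd: separable

  # permuted labels on structureless data: LOOCV error centres at 0.5
  d0 <- make_labeled_matrix(n_genes = 50, n_per = 6, delta = 0,
                            noise_sd = 0.5, seed = 240)
  set.seed(25)
  rates <- vapply(1:100, function(i) {
    perm <- sample(d0$labels)
    names(perm) <- names(d0$labels)
    suppressMessages(bccp_loocv(d0$x, perm, rownames(d0$x$values)))$rate
  }, 1)
  expect_lt(abs(mean(rates) - 0.5), 0.1)
})

test_that("tri-state classification follows the posterior cutoffs", {
  d <- make_labeled_matrix(n_genes = 40, n_per = 6, delta = 2,
                           noise_sd = 0.5, seed = 26)
  model <- bccp_fit(d$x, d$labels, rownames(d$x$values))
  set.seed(27)
  cohort_v <- matrix(rnorm(40 * 50, 8, 0.5), 40,
                     dimnames = list(rownames(d$x$values),
                                     sprintf("P%02d", 1:50)))
  cohort_v[, 26:50] <- cohort_v[, 26:50] + 2
  cohort <- expression_matrix(cohort_v, rep("patient", 50))
  cls <- bccp_classify(model, cohort)
  manual <- ifelse(cls$p_high > 0.7, "high",
                   ifelse(cls$p_high < 0.3, "low", "undetermined"))
  expect_identical(cls$label, manual)
  expect_lt(mean(cls$label == "undetermined"), 0.05)

  # degenerate cutoffs low = high = 0.5: nothing undetermined
  cls5 <- bccp_classify(model, cohort, cutoffs = c(low = 0.5, high = 0.5))
  expect_false(any(cls5$label == "undetermined"))

  tiny <- expression_matrix(
    matrix(rnorm(10), 1, 10,
           dimnames = list("g001", sprintf("P%02d", 1:10))),
    rep("patient", 10))
  expect_error(bccp_classify(model, tiny), "matched")
})

test_that("models survive a JSON round trip", {
  d <- make_labeled_matrix(seed = 28)
  model <- bccp_fit(d$x, d$labels, rownames(d$x$values))
  path <- file.path(tempdir(), "model.json")
  bccp_to_json(model, path)
  back <- bccp_from_json(path)
  cc <- seq(-3, 3, length.out = 7)
  expect_equal(bccp_posterior(back, cc), bccp_posterior(model, cc),
               tolerance = 1e-12)
  expect_equal(back$genes, model$genes)
  expect_equal(unname(back$weights), unname(model$weights))
})

test_that("fit validates labels, classes and variance", {
  d <- make_labeled_matrix(seed = 29)
  all_high <- setNames(rep("high", 12), names(d$labels))
  expect_error(bccp_fit(d$x, all_high, rownames(d$x$values)),
               "single-class")
  bad <- d$labels; bad[1] <- "maybe"
  expect_error(bccp_fit(d$x, bad, rownames(d$x$values)), "high")
  expect_error(bccp_fit(d$x, d$labels, rownames(d$x$values),
                        cutoffs = c(low = 0.8, high = 0.7)), "cutoffs")
})

test_that("planted cohort subtypes are recovered through classification", {
  # train on a labelled panel, classify an n = 285 cohort
  co <- generate_cohort(cohort_design(n_patients = 285, delta_sig = 1,
                                      noise_sd = 0.5, seed = 30))
  train <- generate_experiment(experiment_design(
    conditions = c("low", "high"),
    nc886_level = c(low = "low", high = "high"),
    collection = gene_set_collection(
      list(SIG = co$truth$signature_genes), "SIG"),
    planted = list(high = list(sets = "SIG", delta = 1)),
    replicates = 6, n_genes = 400, noise_sd = 0.5, seed = 31))
  model <- suppressMessages(bccp_fit(train$matrix, train$matrix$condition,
                                     co$truth$signature_genes))
  cls <- bccp_classify(model, co$matrix)
  det <- cls$label != "undetermined"
  agree <- mean(cls$label[det] ==
                  co$truth$subtype[cls$sample[det]])
  expect_gte(agree, 0.9)
})
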