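test_that("set Z-score follows the parametric formula on analytic fixtures", {
  # whole universe as the set: S_m = mu, z = 0
  ct <- fake_contrast(paste0("g", 1:10), fc = rnorm(10))
  expect_equal(set_zscore(ct, ct$gene)$z, 0)

  # members at fc 1 against a background with mean 0, sd ~1:
  # z = (1 - 0) * sqrt(4) / 1 = 2
  genes <- c(paste0("m", 1:4), paste0("b", 1:796))
  fc <- c(rep(1, 4), rep(1, 396), rep(-1, 400))  # overall mean 0
  ct <- fake_contrast(genes, fc)
  res <- set_zscore(ct, paste0("m", 1:4), min_set_size = 4)
  expect_equal(res$m, 4L)
  expect_equal(res$z, 2, tolerance = 2e-3)  # sample sd = sqrt(800/799)
  # exact against independently recomputed formula
  expect_equal(res$z, (mean(fc[1:4]) - mean(fc)) * 2 / sd(fc),
               tolerance = 1e-12)

  expect_error(set_zscore(ct, paste0("m", 1:3), min_set_size = 5),
               "min_set_size")
  flat <- fake_contrast(genes, rep(0.3, 800))
  expect_error(set_zscore(flat, paste0("m", 1:4), min_set_size = 4),
               "degenerate")
})

test_that("random set Z-scores on a null contrast are standard normal", {
  coll <- random_collection(1, 10, 10000, seed = 5)
  e <- generate_experiment(experiment_design(
    conditions = c("ctl", "trt"),
    nc886_level = c(ctl = "low", trt = "high"),
    collection = coll, n_genes = 10000, seed = 17))
  ct <- contrast(e$matrix, "trt", "ctl")
  set.seed(18)
  z <- vapply(1:2000, function(i)
    set_zscore(ct, sample(ct$gene, 50))$z, 1)
  expect_lt(abs(mean(z)), 0.05)
  expect_gte(sd(z), 0.95)
  expect_lte(sd(z), 1.05)
})

test_that("profiles negate exactly under contrast reversal", {
  panel <- sim_mir_panel(seed = 3, n_sets = 40, set_size = 20,
                         n_genes = 2000, n_experiments = 1)
  e <- generate_experiment(experiment_design(
    conditions = c("control", "treated"),
    nc886_level = c(control = "low", treated = "high"),
    collection = panel$mir,
    planted = list(treated = list(sets = panel$planted, delta = 0.5)),
    n_genes = 2000, seed = 3010))
  fwd <- suppressMessages(
    profile_collection(contrast(e$matrix, "treated", "control"), panel$mir))
  rev <- suppressMessages(
    profile_collection(contrast(e$matrix, "control", "treated"), panel$mir))
  expect_equal(rev$z, -fwd$z)
  rd_f <- rank_distribution(fwd); rd_r <- rank_distribution(rev)
  expect_equal(rd_r$n_depleted, rd_f$n_enriched)
  expect_equal(rd_r$n_enriched, rd_f$n_depleted)
})

test_that("a planted set tops its profile across seeded runs", {
  hits <- vapply(1:20, function(s) {
    panel <- sim_mir_panel(seed = 100 + s, n_sets = 50, set_size = 50,
                           n_genes = 4000, n_planted = 1, delta = 0.5,
                           n_experiments = 1)
    p <- panel$profiles[[1]]
    p$set[which.max(p$z)] == panel$planted
  }, TRUE)
  expect_gte(sum(hits), 19)
})

test_that("rank distributions count depleted, enriched and zero sets", {
  p <- fake_profile(paste0("S", 1:5), c(-2, -1, 0.5, 1, 3))
  rd <- rank_distribution(p)
  expect_equal(rd$n_depleted, 2L)
  expect_equal(rd$n_enriched, 3L)
  expect_equal(rd$x_intercept_rank, 3L)
  expect_equal(unname(rd$z), sort(p$z))

  all_neg <- rank_distribution(fake_profile(paste0("S", 1:4),
                                            c(-3, -2, -1, -0.5)))
  expect_equal(all_neg$x_intercept_rank, 5L)

  with_zero <- rank_distribution(fake_profile(paste0("S", 1:3),
                                              c(-1, 0, 1)))
  expect_equal(with_zero$n_zero, 1L)
  expect_equal(with_zero$n_depleted, 1L)
  expect_equal(with_zero$n_enriched, 1L)
})

test_that("profile comparison reports r, F-test p and quadrant counts", {
  pa <- fake_profile(paste0("S", 1:4), c(-2, -1, 1, 2))
  pb <- fake_profile(paste0("S", 1:4), c(1, 2, -1, -3))
  cmp <- compare_profiles(pa, pb)
  # frozen from independent computation on the paired z values
  expect_equal(cmp$pearson_r, -0.9057257, tolerance = 1e-6)
  expect_equal(unname(cmp$quadrants),
               c(0L, 2L, 0L, 2L))  # all mass in QII and QIV

  neg <- fake_profile(paste0("S", 1:4), -pa$z)
  expect_equal(compare_profiles(pa, neg)$pearson_r, -1)
  expect_equal(sum(compare_profiles(pa, neg)$quadrants[c("Q2", "Q4")]), 4L)
  expect_equal(compare_profiles(pa, pa)$pearson_r, 1)
  expect_error(compare_profiles(fake_profile("S1", 1), fake_profile("S1", 1)),
               "fewer than 3")
})

test_that("oriented Z sums rank sets with ties broken by name", {
  p1 <- fake_profile(c("B", "A", "C"), c(3, 1, -2))
  single <- rank_mirs(list(p1))
  expect_equal(single$set, c("B", "A", "C"))
  expect_equal(single$score, c(3, 1, -2))

  p2 <- fake_profile(c("B", "A", "C"), -c(3, 1, -2))
  two <- rank_mirs(list(p1, p2), orientations = c(1, -1))
  expect_equal(two$score[two$set == "B"], 6)

  p3 <- fake_profile(c("B", "A"), c(1, 1))
  expect_message(res <- rank_mirs(list(p1, p3)), "excluded 1")
  expect_equal(res$set, c("B", "A"))  # C dropped; B = 4 outranks A = 2

  tied <- rank_mirs(list(fake_profile(c("ZZ", "AA"), c(1, 1))))
  expect_equal(tied$set, c("AA", "ZZ"))  # equal scores: name order
})

test_that("the planted set's expected Z rises monotonically with the shift", {
  mean_z <- vapply(c(0, 0.25, 0.5, 1), function(delta) {
    z <- vapply(1:3, function(s) {
      coll <- random_collection(10, 50, 2000, seed = 700 + s)
      e <- generate_experiment(experiment_design(
        conditions = c("ctl", "trt"),
        nc886_level = c(ctl = "low", trt = "high"),
        collection = coll,
        planted = if (delta > 0)
          list(trt = list(sets = names(coll$sets)[1], delta = delta)),
        n_genes = 2000, seed = 800 + s))
      p <- suppressMessages(
        profile_collection(contrast(e$matrix, "trt", "ctl"), coll))
      p$z[p$set == names(coll$sets)[1]]
    }, 1)
    mean(z)
  }, 1)
  expect_true(all(diff(mean_z) > 0))
})
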