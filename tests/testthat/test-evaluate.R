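test_that("ROC handles the canonical separation cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(0, 0, 1, 1))$auc, 0.0)
  expect_equal(roc_auc(c(0.5, 0.5, 0.2, 0.8), c(1, 0, 0, 1))$auc, 0.875)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals pair counting on tied random instances", {
  set.seed(101)
  max_diff <- 0
  for (i in 1:300) {
    n <- sample(6:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    curve <- roc_auc(scores, labels)
    max_diff <- max(max_diff,
                    abs(curve$auc - brute_force_auc(scores, labels)),
                    abs(curve$auc - mcitransfer:::auc_rank(scores, labels)))
  }
  expect_lt(max_diff, 1e-12)
})

test_that("AUC agrees with pROC and survives monotone transforms", {
  set.seed(7)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  mine <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
  expect_equal(roc_auc(plogis(scores), labels)$auc, mine)
  expect_equal(roc_auc(exp(scores), labels)$auc, mine)
})

test_that("operating point maximizes balanced accuracy like the oracle", {
  # perfect separation
  op <- operating_point(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$accuracy, 1)

  set.seed(55)
  for (i in 1:60) {
    scores <- round(runif(20), 2)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 18, replace = TRUE))
    op <- operating_point(roc_auc(scores, labels))
    oracle <- brute_force_operating_point(scores, labels)
    expect_equal(op$balanced_accuracy, oracle$bacc, tolerance = 1e-12)
    expect_equal(op$sensitivity, oracle$sens, tolerance = 1e-12)
    expect_equal(op$specificity, oracle$spec, tolerance = 1e-12)
  }
})

test_that("accuracy is the raw prevalence-weighted value", {
  # printed study arithmetic: sens 0.594 / spec 0.658 at 48 cases, 617
  # controls gives accuracy 0.653
  acc <- (0.594 * 48 + 0.658 * 617) / 665
  expect_equal(round(acc, 3), 0.653)
  curve <- roc_auc(c(1, 0), c(1, 0))
  got <- operating_point(curve, n_pos = 48, n_neg = 617)
  expect_equal(got$accuracy, (1 * 48 + 1 * 617) / 665)
})

test_that("paired bootstrap AUC comparison behaves at the boundaries", {
  set.seed(2)
  labels <- rep(c(1, 0), each = 100)
  s1 <- c(rnorm(100, 2), rnorm(100))   # separates well
  s2 <- runif(200)                     # noise
  same <- bootstrap_paired_auc_test(s1, s1, labels, n_boot = 200, seed = 3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  diff <- bootstrap_paired_auc_test(s1, s2, labels, n_boot = 1000, seed = 3)
  expect_lt(diff$p_value, 0.01)
  expect_gt(diff$statistic, 0.3)

  again <- bootstrap_paired_auc_test(s1, s2, labels, n_boot = 1000,
                                     seed = 3)
  expect_identical(diff$p_value, again$p_value)
  expect_error(bootstrap_paired_auc_test(s1, s2[-1], labels), "length")
})

test_that("max-statistic permutation test attains its analytic minimum", {
  set.seed(4)
  labels <- rep(c(1, 0), each = 20)
  perfect <- as.numeric(labels) + rnorm(40, sd = 0.01)
  res <- permutation_vs_chance(list(m = perfect), labels, n_perm = 999,
                               seed = 5)
  expect_equal(res$m$p_value, 1 / 1000)
  # with one model, adjusted equals unadjusted
  expect_equal(res$m$p_value, res$m$p_unadjusted)
})

test_that("max-statistic adjustment dominates the unadjusted p", {
  set.seed(6)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(1, 0)
  sets <- lapply(1:4, function(i) rnorm(60))
  names(sets) <- paste0("m", 1:4)
  res <- permutation_vs_chance(sets, labels, n_perm = 300, seed = 7)
  for (m in names(sets)) {
    expect_gte(res[[m]]$p_value, res[[m]]$p_unadjusted)
    expect_gte(res[[m]]$p_value, 1 / 301)
  }
})

test_that("rank-sum test matches exact enumeration and the norm approx", {
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(ranksum_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  # agreement with the reference implementation in the tie-free case
  set.seed(8)
  a <- rnorm(25)
  b <- rnorm(30, 0.3)
  mine <- ranksum_test(a, b)
  ref <- stats::wilcox.test(a, b, correct = FALSE, exact = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  # large shift is detected decisively
  big <- ranksum_test(rnorm(200), rnorm(200, 1))
  expect_lt(big$p_value, 1e-6)
  expect_error(ranksum_test(numeric(0), 1:3), "nonempty")
})

test_that("offset correction is a pure monotone shift", {
  expect_equal(offset_correct(c(0.2, 0.5, 0.9)), c(0.0, 0.3, 0.7))
  expect_equal(offset_correct(rep(0.4, 5)), rep(0, 5))
  set.seed(9)
  s <- runif(50)
  l <- rbinom(50, 1, 0.5)
  l[1:2] <- c(1, 0)
  expect_equal(roc_auc(offset_correct(s), l)$auc, roc_auc(s, l)$auc)
  expect_equal(min(offset_correct(s)), 0)
})

test_that("overlap statistic maps AUC to distributional overlap", {
  expect_equal(overlap_statistic(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 0)
  expect_equal(overlap_statistic(c(0.9, 0.8, 0.3, 0.2), c(0, 0, 1, 1)), 0)
  expect_equal(overlap_statistic(c(1, 2, 1, 2), c(1, 0, 0, 1)), 1)
  expect_equal(overlap_statistic(c(0.5, 0.5, 0.2, 0.8), c(1, 0, 0, 1)),
               0.25)
})

test_that("overlap permutation test separates clear cases and respects
           Bonferroni", {
  set.seed(10)
  n <- 200
  labels <- rep(c(1, 0), each = n / 2)
  noisy <- rnorm(n)                                  # AUC ~ 0.5, overlap ~1
  sharp <- as.numeric(labels) * 3 + rnorm(n)         # AUC ~ 0.98
  res <- overlap_permutation_test(noisy, labels, sharp, labels,
                                  n_perm = 500, seed = 11)
  expect_lt(res$p_unadjusted, 0.01)
  expect_gt(res$statistic, 0.5)

  res3 <- overlap_permutation_test(noisy, labels, sharp, labels,
                                   n_perm = 500, n_comparisons = 3,
                                   seed = 11)
  expect_equal(res3$p_value, min(1, res3$p_unadjusted * 3))
  expect_identical(res3$adjustment, "bonferroni")
})

test_that("overlap test is calibrated under exchangeability", {
  set.seed(12)
  labels <- rep(c(1, 0), each = 60)
  hits <- 0
  runs <- 60
  for (i in seq_len(runs)) {
    pool <- rnorm(240) + 0.8 * rep(rep(c(1, 0), each = 60), 2)
    s1 <- pool[1:120]
    s2 <- pool[121:240]
    p <- overlap_permutation_test(s1, labels, s2, labels, n_perm = 150,
                                  seed = i)$p_unadjusted
    hits <- hits + (p <= 0.05)
  }
  expect_lte(hits / runs, 0.05 + 2 * sqrt(0.05 * 0.95 / runs) + 0.02)
})

test_that("resampling p-values are always strictly positive", {
  set.seed(13)
  labels <- rep(c(1, 0), 25)
  s <- as.numeric(labels) + rnorm(50, sd = 0.01)
  p1 <- bootstrap_paired_auc_test(s, rev(s), labels, n_boot = 99,
                                  seed = 1)$p_value
  p2 <- permutation_vs_chance(list(a = s), labels, n_perm = 99,
                              seed = 1)$a$p_value
  p3 <- overlap_permutation_test(s, labels, rnorm(50), labels,
                                 n_perm = 99, seed = 1)$p_unadjusted
  expect_true(all(c(p1, p2, p3) >= 1 / 100))
})
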