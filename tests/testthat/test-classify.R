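test_that("standardizer matches closed forms and records constants", {
  vals <- cbind(GMD_001 = c(1, 2, 3), GMD_002 = c(5, 5, 5))
  std <- fit_standardizer(vals)
  out <- apply_standardizer(std, vals)
  expect_equal(out[, "GMD_001"], c(-1, 0, 1))
  expect_equal(out[, "GMD_002"], c(0, 0, 0))
  expect_identical(std$constant_features, "GMD_002")

  held <- cbind(GMD_001 = c(1, 2, 3), GMD_002 = c(9, 9, 9))
  expect_equal(apply_standardizer(std, held)[, "GMD_001"], c(-1, 0, 1))
})

test_that("training standardization yields zero mean and unit variance", {
  set.seed(1)
  vals <- matrix(rnorm(50 * 8, mean = 3, sd = 2), 50, 8,
                 dimnames = list(NULL, sprintf("FA_%03d", 1:8)))
  out <- apply_standardizer(fit_standardizer(vals), vals)
  expect_lt(max(abs(colMeans(out))), 1e-10)
  expect_lt(max(abs(apply(out, 2, sd) - 1)), 1e-10)
})

make_logit_data <- function(n = 200, p = 5, seed = 42, covariates = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("GMD_%03d", seq_len(p))))
  cov <- if (covariates) {
    cbind(age = rnorm(n, 0, 8), sex = rbinom(n, 1, 0.5))
  } else NULL
  beta <- c(0.8, -0.6, 0.4, 0, 0)[seq_len(p)]
  eta <- drop(x %*% beta) + if (covariates) 0.03 * cov[, "age"] else 0
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y, cov = cov)
}

test_that("an unpenalized fit reproduces the maximum-likelihood solution", {
  d <- make_logit_data()
  fit <- fit_penalized_logistic(d$x, d$y, d$cov, alpha = 0.5, lambda = 0)
  oracle <- stats::glm(d$y ~ d$x + d$cov, family = stats::binomial())
  expect_lt(max(abs(c(fit$intercept, fit$beta, fit$gamma) -
                      unname(coef(oracle)))), 1e-4)
})

test_that("a huge penalty zeroes features but keeps covariate MLE", {
  d <- make_logit_data()
  fit <- fit_penalized_logistic(d$x, d$y, d$cov, alpha = 0.5, lambda = 1e6)
  expect_lt(max(abs(fit$beta)), 1e-8)
  oracle <- stats::glm(d$y ~ d$cov, family = stats::binomial())
  expect_lt(max(abs(c(fit$intercept, fit$gamma) - unname(coef(oracle)))),
            1e-4)
})

test_that("the analytic lambda_max bounds the lasso active set", {
  d <- make_logit_data(seed = 7)
  fit0 <- stats::glm(d$y ~ d$cov, family = stats::binomial())
  lmax <- max(abs(crossprod(d$x, d$y - fitted(fit0)))) / length(d$y)
  fit_above <- fit_penalized_logistic(d$x, d$y, d$cov, alpha = 1,
                                      lambda = lmax * 1.001)
  expect_lt(max(abs(fit_above$beta)), 1e-8)
  fit_below <- fit_penalized_logistic(d$x, d$y, d$cov, alpha = 1,
                                      lambda = lmax * 0.8)
  expect_gt(max(abs(fit_below$beta)), 0)
})

test_that("degenerate inputs are rejected", {
  d <- make_logit_data()
  expect_error(fit_penalized_logistic(d$x, rep(1, nrow(d$x)), d$cov,
                                      alpha = 0.5, lambda = 0.1),
               "single class")
  bad <- d$x
  bad[1, 1] <- Inf
  expect_error(fit_penalized_logistic(bad, d$y, d$cov, alpha = 0.5,
                                      lambda = 0.1), "non-finite")
})

test_that("probability predictions follow the logistic closed form", {
  model <- structure(
    list(alpha = 0.5, lambda = 0.1,
         beta = c(GMD_001 = 0.7, GMD_002 = -1.2), gamma = numeric(0),
         intercept = 0.3),
    class = "pen_logit")
  x <- cbind(GMD_001 = c(1, 0, -2), GMD_002 = c(0.5, 2, 1))
  expected <- plogis(0.3 + x %*% c(0.7, -1.2))
  expect_equal(predict_probability(model, x), drop(expected),
               tolerance = 1e-12)

  model$beta[] <- 0
  model$intercept <- 0
  expect_equal(predict_probability(model, x), rep(0.5, 3))
  model$intercept <- 1e3
  expect_true(all(predict_probability(model, x) > 1 - 1e-10))

  # glmnet's own predictions agree with the stored-coefficient arithmetic
  d <- make_logit_data(seed = 11)
  fit <- fit_penalized_logistic(d$x, d$y, d$cov, alpha = 0.5, lambda = 0.05)
  mine <- predict_probability(fit, d$x, d$cov)
  expect_true(all(mine > 0 & mine < 1))
})

test_that("the regularization path is monotone in the l1 norm", {
  d <- make_logit_data(seed = 3)
  lams <- c(0.001, 0.005, 0.02, 0.05, 0.1, 0.3)
  norms <- vapply(lams, function(l) {
    sum(abs(fit_penalized_logistic(d$x, d$y, d$cov, alpha = 1,
                                   lambda = l)$beta))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("nested CV scores every subject exactly once per repetition", {
  cp <- generate_cohorts(small_config(seed = 31))
  cv <- nested_cv(cp$a, "mild_ad", k_outer = 5, k_inner = 5,
                  repetitions = 2, alpha_grid = c(0.5), nlambda = 10,
                  seed = 4)
  expect_false(anyNA(cv$oof_scores))
  expect_equal(dim(cv$oof_scores), c(100, 2))
  expect_true(all(cv$auc_per_repetition >= 0 &
                    cv$auc_per_repetition <= 1))
  expect_equal(nrow(cv$chosen_params), 10)
  # per repetition each subject appears in exactly one outer test fold
  for (r in 1:2) {
    expect_equal(sort(unique(cv$folds[[r]])), 1:5)
    expect_equal(length(cv$folds[[r]]), 100)
  }
  # determinism
  cv2 <- nested_cv(cp$a, "mild_ad", k_outer = 5, k_inner = 5,
                   repetitions = 2, alpha_grid = c(0.5), nlambda = 10,
                   seed = 4)
  expect_identical(cv$oof_scores, cv2$oof_scores)
})

test_that("nested CV recovers strong signal and stays honest under null", {
  cp <- generate_cohorts(small_config(seed = 32, effect_size_base = 2))
  cv <- nested_cv(cp$a, "mild_ad", k_outer = 5, k_inner = 5,
                  repetitions = 2, alpha_grid = c(0.1, 1), nlambda = 15,
                  seed = 6)
  expect_gt(mean(cv$auc_per_repetition), 0.9)

  shuffled <- cp$a
  set.seed(99)
  shuffled$subjects$group <- sample(shuffled$subjects$group)
  cv0 <- nested_cv(shuffled, "mild_ad", k_outer = 5, k_inner = 5,
                   repetitions = 3, alpha_grid = c(0.5), nlambda = 15,
                   seed = 6)
  expect_lt(abs(mean(cv0$auc_per_repetition) - 0.5), 0.12)
})

test_that("no information leaks from outer test folds into training", {
  cp <- generate_cohorts(small_config(seed = 33))
  folds <- list(local({
    set.seed(12)
    mcitransfer:::stratified_folds(
      cp$a$subjects$group %in% "mild_ad", 5)
  }))
  cv <- nested_cv(cp$a, "mild_ad", k_outer = 5, k_inner = 5,
                  repetitions = 1, alpha_grid = c(0.5), nlambda = 10,
                  seed = 8, folds = folds)
  # make one subject's features extreme; its fold-mates' scores are
  # untouched because neither standardizer nor model saw the test fold
  s <- which(folds[[1]] == 3)[1]
  mates <- setdiff(which(folds[[1]] == 3), s)
  poked <- cp$a
  poked$values[s, ] <- poked$values[s, ] + 1e4
  cv_poked <- nested_cv(poked, "mild_ad", k_outer = 5, k_inner = 5,
                        repetitions = 1, alpha_grid = c(0.5), nlambda = 10,
                        seed = 8, folds = folds)
  expect_equal(cv_poked$oof_scores[mates, 1], cv$oof_scores[mates, 1],
               tolerance = 1e-12)
  # flipping a test subject's label cannot move its own score either
  # (folds frozen so only the label changes, not the partition)
  sp <- which(folds[[1]] == 3 & cp$a$subjects$group == "mild_ad")[1]
  flipped <- cp$a
  flipped$subjects$group[sp] <- "control"
  cv_flip <- nested_cv(flipped, "mild_ad", k_outer = 5, k_inner = 5,
                       repetitions = 1, alpha_grid = c(0.5), nlambda = 10,
                       seed = 8, folds = folds)
  expect_equal(cv_flip$oof_scores[sp, 1], cv$oof_scores[sp, 1],
               tolerance = 1e-12)
})

test_that("repetition-to-repetition AUC variance shrinks with sample size", {
  sizes <- c(60, 240)
  sds <- vapply(sizes, function(n) {
    cp <- generate_cohorts(small_config(
      seed = 34,
      group_sizes = list(A = c(control = n, mild_ad = n / 2),
                         B = c(control = 20, mci_amnestic = 5,
                               mci_nonamnestic = 5))))
    cv <- nested_cv(cp$a, "mild_ad", k_outer = 5, k_inner = 5,
                    repetitions = 6, alpha_grid = c(0.5), nlambda = 10,
                    seed = 3)
    sd(cv$auc_per_repetition)
  }, numeric(1))
  expect_lt(sds[2], sds[1] + 0.02)
})

test_that("measure-set selection finds the signal-bearing block", {
  cfg <- small_config(seed = 35, effect_size_base = 1.5)
  cp <- generate_cohorts(cfg)
  # confine the signal to the GMD block by undoing the mild pattern on all
  # other blocks (mild-vs-control subset, where the construction is exact)
  flat <- ft_subset(cp$a, cp$a$subjects$group %in% c("control", "mild_ad"))
  pat <- cp$truth$pattern_mild
  non_gmd <- names(pat)[!startsWith(names(pat), "GMD")]
  rows <- flat$subjects$group == "mild_ad"
  shift <- cfg$severity_multipliers[["mild_ad"]] * cfg$effect_size_base *
    cfg$noise_sd * pat[non_gmd]
  flat$values[rows, non_gmd] <-
    sweep(flat$values[rows, non_gmd, drop = FALSE], 2, shift, "-")
  results <- lapply(
    stats::setNames(c("multiparametric", "GMD", "WMD"),
                    c("multiparametric", "GMD", "WMD")),
    function(ms) nested_cv(flat, "mild_ad", measure_set = ms,
                           k_outer = 5, k_inner = 5, repetitions = 1,
                           alpha_grid = c(0.5), nlambda = 15, seed = 2))
  sel <- select_measure_set(results)
  means <- stats::setNames(sel$table$mean_auc, sel$table$measure_set)
  expect_lt(means[["WMD"]], 0.7)
  expect_gt(means[["GMD"]], 0.8)
  expect_gt(means[["multiparametric"]], means[["WMD"]])
  expect_true(sel$chosen %in% c("GMD", "multiparametric"))
})

test_that("models and CV results serialize faithfully", {
  cp <- generate_cohorts(small_config(seed = 36))
  model <- train_classifier(cp$a, c("mild_ad", "moderate_ad"),
                            alpha_grid = c(0.5), k_inner = 5,
                            nlambda = 10, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(back$beta), model$beta, tolerance = 1e-12)
  expect_equal(back$alpha, model$alpha)
  expect_equal(back$lambda, model$lambda)
  expect_equal(unlist(back$standardization$mean),
               model$standardization$mean, tolerance = 1e-12)

  cv <- nested_cv(cp$a, "mild_ad", k_outer = 5, k_inner = 5,
                  repetitions = 2, alpha_grid = c(0.5), nlambda = 10,
                  seed = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cv_result(cv, f1, f2)
  long <- utils::read.csv(f1)
  expect_equal(nrow(long), 100 * 2)
  expect_equal(
    long$score[long$repetition == 2],
    unname(cv$oof_scores[, 2]), tolerance = 1e-12)
  summ <- utils::read.csv(f2)
  expect_equal(summ$auc, cv$auc_per_repetition, tolerance = 1e-12)
})

test_that("measure-set ties resolve in the declared preference order", {
  mk <- function(ms, aucs) {
    structure(list(auc_per_repetition = aucs, measure_set = ms),
              class = "cv_result")
  }
  sel <- select_measure_set(list(
    FA = mk("FA", c(0.7, 0.7)), multiparametric = mk("multiparametric",
                                                     c(0.7, 0.7)),
    GMD = mk("GMD", c(0.7, 0.7))))
  expect_identical(sel$chosen, "multiparametric")
  sel2 <- select_measure_set(list(FA = mk("FA", 0.7), GMD = mk("GMD", 0.7)))
  expect_identical(sel2$chosen, "GMD")
  expect_error(select_measure_set(list()), "no candidate")
})
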