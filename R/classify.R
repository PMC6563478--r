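#' Fit a feature standardizer
#'
#' Records per-feature training mean and sample SD (n - 1 denominator).
#' Features with zero training variance are flagged and later mapped to 0
#' rather than failing the fit.
#'
#' @param values numeric training matrix with feature-id column names.
#' @return An object of class `standardizer` with `mean`, `sd` and
#'   `constant_features`.
#' @export
fit_standardizer <- function(values) {
  if (nrow(values) < 2) {
    stop("need at least 2 training rows to standardize", call. = FALSE)
  }
  m <- colMeans(values)
  s <- apply(values, 2, stats::sd)
  constant <- colnames(values)[s < 1e-12]
  s[s < 1e-12] <- 1  # placeholder; constant columns are zeroed on apply
  structure(list(mean = m, sd = s, constant_features = constant),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param params a [fit_standardizer()] result.
#' @param values matrix with the same feature columns (any rows).
#' @return Matrix of `(value - mean) / sd`; constant training features are
#'   mapped to 0.
#' @export
apply_standardizer <- function(params, values) {
  if (!identical(colnames(values), names(params$mean))) {
    stop("feature ids do not match the standardizer", call. = FALSE)
  }
  out <- sweep(sweep(values, 2, params$mean, "-"), 2, params$sd, "/")
  if (length(params$constant_features) > 0) {
    out[, params$constant_features] <- 0
  }
  out
}

# Largest penalty with every penalized coefficient at zero: with covariates
# (and intercept) unpenalized, the score of each feature at the
# covariate-only MLE gives lambda_max = max_j |x_j' (y - p_hat)| / (n * alpha).
lambda_max_penalized <- function(x, y, covariates = NULL, alpha) {
  n <- length(y)
  if (is.null(covariates) || ncol(covariates) == 0) {
    p_hat <- rep(mean(y), n)
  } else {
    fit0 <- stats::glm.fit(cbind(1, covariates), y,
                           family = stats::binomial())
    p_hat <- fit0$fitted.values
  }
  max(abs(crossprod(x, y - p_hat))) / (n * max(alpha, 0.001))
}

#' Fit an elastic-net logistic model with unpenalized covariates
#'
#' Minimizes the mean negative binomial log-likelihood plus
#' `lambda * ((1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1)` over the
#' feature coefficients, leaving the intercept and any covariate
#' coefficients (age, sex) unpenalized. The solver is glmnet's coordinate
#' descent; the requested `lambda` is embedded in a decreasing path for
#' stable convergence and the covariate penalty exemption is rescaled so
#' the feature penalty equals the nominal `lambda` exactly.
#'
#' @param x standardized feature matrix (column names = feature ids).
#' @param y binary response (0/1 or logical), both classes present.
#' @param covariates optional numeric matrix of unpenalized covariates.
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param lambda penalty strength (>= 0).
#' @param thresh coordinate-descent convergence threshold.
#' @return An object of class `pen_logit` with `beta` (features), `gamma`
#'   (covariates), `intercept`, `alpha`, `lambda`; slots `standardization`,
#'   `age_center` and `measure_set` are filled by the training wrappers.
#' @export
fit_penalized_logistic <- function(x, y, covariates = NULL, alpha, lambda,
                                   thresh = 1e-11) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("degenerate labels: response contains a single class",
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  p <- ncol(x)
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  xfull <- if (q > 0) cbind(x, covariates) else x
  # glmnet rescales penalty.factor to sum to nvars; pre-scale lambda so the
  # effective feature penalty is the nominal one.
  pf <- c(rep(1, p), rep(0, q))
  lam_scale <- if (q > 0) p / (p + q) else 1
  lmax <- lambda_max_penalized(x, y, covariates, alpha)
  lam_hi <- max(lmax * 1.1, lambda, 1e-4)
  lam_lo <- max(lambda, lam_hi * 1e-6)
  path <- exp(seq(log(lam_hi), log(lam_lo), length.out = 30))
  path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(xfull, y, family = "binomial",
                        alpha = alpha, lambda = path * lam_scale,
                        standardize = FALSE, penalty.factor = pf,
                        thresh = thresh, maxit = 10^7)
  j <- match(TRUE, abs(fit$lambda / lam_scale - lambda) < 1e-12)
  if (is.na(j)) j <- which.min(abs(fit$lambda / lam_scale - lambda))
  coefs <- as.numeric(fit$beta[, j])
  structure(
    list(alpha = alpha, lambda = lambda,
         beta = stats::setNames(coefs[seq_len(p)], colnames(x)),
         gamma = if (q > 0) {
           stats::setNames(coefs[p + seq_len(q)], colnames(covariates))
         } else numeric(0),
         intercept = fit$a0[[j]],
         standardization = NULL, age_center = NULL, measure_set = NULL),
    class = "pen_logit"
  )
}

#' Predicted class-1 probability scores
#'
#' Computes `plogis(intercept + x beta + covariates gamma)` from the stored
#' coefficients; every score lies strictly between 0 and 1 and reads as a
#' disease-similarity probability (0 = control-like, 1 = case-like).
#'
#' @param model a [fit_penalized_logistic()] result.
#' @param x standardized feature matrix matching the model's feature ids.
#' @param covariates covariate matrix matching the model's `gamma` names
#'   (omit when the model has none).
#' @return Numeric probability vector.
#' @export
predict_probability <- function(model, x, covariates = NULL) {
  if (!identical(colnames(x), names(model$beta))) {
    stop("feature ids do not match the model", call. = FALSE)
  }
  eta <- model$intercept + drop(x %*% model$beta)
  if (length(model$gamma) > 0) {
    if (is.null(covariates) ||
        !identical(colnames(covariates), names(model$gamma))) {
      stop("covariates do not match the model", call. = FALSE)
    }
    eta <- eta + drop(covariates %*% model$gamma)
  }
  stats::plogis(eta)
}

# Covariate matrix used by all models: age centered at the training mean
# (stabilizes the intercept), sex as 0/1. Unpenalized, so scale-free.
covariate_matrix <- function(subjects, age_center) {
  cbind(age = subjects$age - age_center, sex = subjects$sex)
}

# Inner cross-validated selection of (alpha, lambda), maximizing the AUC of
# pooled out-of-fold scores. One lambda path per alpha, anchored at the
# analytic lambda_max of the full data handed in. Ties prefer the sparser
# model (larger lambda), then the earlier alpha in the grid.
select_hyperparams <- function(xs, y, covariates, alpha_grid, k_inner,
                               nlambda, lambda_min_ratio) {
  n <- length(y)
  fold <- stratified_folds(y, k_inner)
  q <- ncol(covariates)
  pf <- c(rep(1, ncol(xs)), rep(0, q))
  lam_scale <- ncol(xs) / (ncol(xs) + q)
  best <- list(auc = -Inf, alpha = alpha_grid[1], lambda = NA_real_)
  for (alpha in alpha_grid) {
    lmax <- lambda_max_penalized(xs, y, covariates, alpha) * 1.02
    path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
    oof <- matrix(NA_real_, n, length(path))
    for (f in seq_len(k_inner)) {
      tr <- fold != f
      fit <- glmnet::glmnet(cbind(xs, covariates)[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = alpha,
                            lambda = path * lam_scale, standardize = FALSE,
                            penalty.factor = pf, maxit = 5e5)
      pred <- stats::predict(
        fit, cbind(xs, covariates)[!tr, , drop = FALSE], type = "link")
      # pad in case glmnet drops path tail
      oof[!tr, seq_len(ncol(pred))] <- pred
      if (ncol(pred) < length(path)) {
        oof[!tr, seq(ncol(pred) + 1, length(path))] <- pred[, ncol(pred)]
      }
    }
    aucs <- apply(oof, 2, auc_rank, positive = y == 1)
    jbest <- which(aucs >= max(aucs) - 1e-12)[1]  # largest lambda wins ties
    if (aucs[jbest] > best$auc + 1e-12) {
      best <- list(auc = aucs[jbest], alpha = alpha, lambda = path[jbest])
    }
  }
  best
}

#' Train a classifier on a full table with inner-CV tuned hyperparameters
#'
#' Standardizes the selected measure-set features on the training table,
#' centers age at the training mean, selects `(alpha, lambda)` by inner
#' stratified k-fold cross-validation (pooled out-of-fold AUC) and refits
#' on all rows. This is the model that transfer arms apply to the other
#' cohort.
#'
#' @param table training [feature_table()].
#' @param positive_groups diagnostic groups coding the positive class.
#' @param measure_set `"multiparametric"` or a single measure block.
#' @param alpha_grid candidate elastic-net mixing values.
#' @param k_inner inner folds (default 10).
#' @param nlambda,lambda_min_ratio geometry of the per-alpha lambda path.
#' @param seed seed for the inner fold assignment.
#' @return A `pen_logit` carrying its standardizer, age center, measure set
#'   and positive-class definition.
#' @export
train_classifier <- function(table, positive_groups,
                             measure_set = "multiparametric",
                             alpha_grid = seq(0.1, 1, by = 0.1),
                             k_inner = 10, nlambda = 50,
                             lambda_min_ratio = 1e-4, seed = NULL) {
  cols <- measure_set_columns(table, measure_set)
  y <- as.numeric(table$subjects$group %in% positive_groups)
  std <- fit_standardizer(table$values[, cols, drop = FALSE])
  xs <- apply_standardizer(std, table$values[, cols, drop = FALSE])
  age_center <- mean(table$subjects$age)
  cov <- covariate_matrix(table$subjects, age_center)
  if (!is.null(seed)) set.seed(seed)
  sel <- select_hyperparams(xs, y, cov, alpha_grid, k_inner,
                            nlambda, lambda_min_ratio)
  model <- fit_penalized_logistic(xs, y, cov, sel$alpha, sel$lambda)
  model$standardization <- std
  model$age_center <- age_center
  model$measure_set <- measure_set
  model$positive_groups <- positive_groups
  model
}

#' Score a feature table with a trained classifier
#'
#' @param model a [train_classifier()] result.
#' @param table a [feature_table()] sharing the training feature ids.
#' @return Named probability-score vector (one per subject).
#' @export
score_table <- function(model, table) {
  cols <- names(model$standardization$mean)
  xs <- apply_standardizer(model$standardization,
                           table$values[, cols, drop = FALSE])
  cov <- covariate_matrix(table$subjects, model$age_center)
  stats::setNames(predict_probability(model, xs, cov),
                  table$subjects$subject_id)
}

#' Repeated nested stratified k-fold cross-validation
#'
#' Per repetition: a stratified outer k-fold partition; within each outer
#' training set an inner stratified k-fold selects `(alpha, lambda)` by
#' pooled out-of-fold AUC; the tuned model (standardizer and age center fit
#' on the outer training rows only) is refit on the full outer training set
#' and scored on the held-out fold. Every subject is scored exactly once
#' per repetition; nothing from a test fold reaches training.
#'
#' @param table a [feature_table()].
#' @param positive_groups diagnostic groups coding the positive class.
#' @param measure_set `"multiparametric"` or a single measure block.
#' @param k_outer,k_inner outer and inner fold counts (default 10).
#' @param repetitions number of repeated partitions (default 100).
#' @param alpha_grid,nlambda,lambda_min_ratio hyperparameter grid geometry.
#' @param seed master seed; folds and inner selection derive from it.
#' @param folds optional list (length `repetitions`) of precomputed outer
#'   fold assignments, overriding the seeded stratified partition.
#' @return An object of class `cv_result`: `oof_scores` (subjects x
#'   repetitions), `auc_per_repetition`, `chosen_params` (one row per outer
#'   fold per repetition), `folds`, `measure_set`, `positive_groups`.
#' @export
nested_cv <- function(table, positive_groups,
                      measure_set = "multiparametric",
                      k_outer = 10, k_inner = 10, repetitions = 100,
                      alpha_grid = seq(0.1, 1, by = 0.1), nlambda = 50,
                      lambda_min_ratio = 1e-4, seed = 1, folds = NULL) {
  cols <- measure_set_columns(table, measure_set)
  y <- as.numeric(table$subjects$group %in% positive_groups)
  if (length(unique(y)) < 2) {
    stop("degenerate labels: positive class absent", call. = FALSE)
  }
  n <- length(y)
  oof <- matrix(NA_real_, n, repetitions,
                dimnames = list(table$subjects$subject_id, NULL))
  aucs <- numeric(repetitions)
  chosen <- vector("list", repetitions * k_outer)
  fold_list <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    if (is.null(folds)) {
      set.seed(derive_seed(seed, "folds", r))
      fold <- stratified_folds(y, k_outer)
    } else {
      fold <- folds[[r]]
    }
    fold_list[[r]] <- fold
    for (f in seq_len(k_outer)) {
      tr <- fold != f
      std <- fit_standardizer(table$values[tr, cols, drop = FALSE])
      xs_tr <- apply_standardizer(std, table$values[tr, cols, drop = FALSE])
      age_center <- mean(table$subjects$age[tr])
      cov_tr <- covariate_matrix(table$subjects[tr, , drop = FALSE],
                                 age_center)
      set.seed(derive_seed(seed, "inner", r, f))
      sel <- select_hyperparams(xs_tr, y[tr], cov_tr, alpha_grid, k_inner,
                                nlambda, lambda_min_ratio)
      model <- fit_penalized_logistic(xs_tr, y[tr], cov_tr,
                                      sel$alpha, sel$lambda)
      xs_te <- apply_standardizer(std, table$values[!tr, cols, drop = FALSE])
      cov_te <- covariate_matrix(table$subjects[!tr, , drop = FALSE],
                                 age_center)
      oof[!tr, r] <- predict_probability(model, xs_te, cov_te)
      chosen[[(r - 1) * k_outer + f]] <-
        data.frame(repetition = r, fold = f,
                   alpha = sel$alpha, lambda = sel$lambda)
    }
    aucs[r] <- auc_rank(oof[, r], y == 1)
  }
  structure(
    list(oof_scores = oof, auc_per_repetition = aucs,
         chosen_params = do.call(rbind, chosen), folds = fold_list,
         measure_set = measure_set, positive_groups = positive_groups,
         labels = y),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> measure set '%s': mean AUC %.3f [%.3f-%.3f] over %d reps\n",
    x$measure_set, mean(x$auc_per_repetition), min(x$auc_per_repetition),
    max(x$auc_per_repetition), length(x$auc_per_repetition)))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Coefficients keyed by feature id, hyperparameters, covariate
#' coefficients and the standardization state, so a model can be archived
#' or inspected outside R.
#'
#' @param model a `pen_logit`.
#' @param path destination JSON path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    alpha = model$alpha, lambda = model$lambda,
    intercept = model$intercept,
    beta = as.list(model$beta), gamma = as.list(model$gamma),
    measure_set = model$measure_set,
    positive_groups = model$positive_groups,
    age_center = model$age_center,
    standardization = if (!is.null(model$standardization)) {
      list(mean = as.list(model$standardization$mean),
           sd = as.list(model$standardization$sd),
           constant_features = model$standardization$constant_features)
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write cross-validation results to CSV
#'
#' Emits the long per-subject score table (`subject_id`, `repetition`,
#' `score`) and a per-repetition AUC summary.
#'
#' @param cv a [nested_cv()] result.
#' @param scores_path,summary_path destination CSV paths.
#' @return Invisibly, `scores_path`.
#' @export
write_cv_result <- function(cv, scores_path, summary_path) {
  reps <- ncol(cv$oof_scores)
  long <- data.frame(
    subject_id = rep(rownames(cv$oof_scores), reps),
    repetition = rep(seq_len(reps), each = nrow(cv$oof_scores)),
    score = as.vector(cv$oof_scores)
  )
  utils::write.csv(long, scores_path, row.names = FALSE)
  utils::write.csv(
    data.frame(repetition = seq_len(reps), auc = cv$auc_per_repetition),
    summary_path, row.names = FALSE)
  invisible(scores_path)
}

#' Choose the best-performing measure set
#'
#' Compares cross-validation results of candidate measure sets (single
#' blocks and/or the multiparametric combination) evaluated on identical
#' subjects and returns the candidate with the highest mean AUC. Exact ties
#' fall to the earlier candidate in the preference order multiparametric,
#' GMD, DGMV, WMD, FA, MD.
#'
#' @param results named list of [nested_cv()] results, names = candidates.
#' @return List with `chosen` (candidate name) and `table` (per-candidate
#'   mean/min/max AUC, in preference order).
#' @export
select_measure_set <- function(results) {
  if (length(results) == 0) {
    stop("no candidate measure sets supplied", call. = FALSE)
  }
  pref <- c("multiparametric", MEASURE_BLOCKS)
  ord <- order(match(names(results), pref))
  results <- results[ord]
  tab <- data.frame(
    measure_set = names(results),
    mean_auc = vapply(results, function(r) mean(r$auc_per_repetition),
                      numeric(1)),
    min_auc = vapply(results, function(r) min(r$auc_per_repetition),
                     numeric(1)),
    max_auc = vapply(results, function(r) max(r$auc_per_repetition),
                     numeric(1)),
    row.names = NULL
  )
  list(chosen = tab$measure_set[which.max(tab$mean_auc)], table = tab)
}
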