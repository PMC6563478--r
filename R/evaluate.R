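#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (predicting
#' positive at `score >= threshold`) and records the sensitivity /
#' false-positive-rate pairs. The AUC is the trapezoidal area under the
#' resulting curve, which for this construction equals the Mann-Whitney
#' pair-counting statistic (concordant pairs plus half credit for ties).
#'
#' @param scores numeric score vector (higher = more case-like).
#' @param labels binary vector (logical, or 0/1) marking the cases.
#' @return An object of class `roc_curve`: `thresholds` (descending,
#'   starting at `Inf`), `tpr`, `fpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  positive <- as.logical(labels)
  if (length(scores) != length(positive)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate labels: both classes must be present", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[positive] >= t) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!positive] >= t) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f (%d cases / %d controls)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Optimal operating point of a ROC curve
#'
#' Picks the threshold with the highest balanced accuracy
#' `(sensitivity + specificity) / 2`; ties break toward the higher
#' specificity. The reported accuracy is the raw, prevalence-weighted value
#' `(sens * n_pos + spec * n_neg) / (n_pos + n_neg)` at that threshold.
#'
#' @param curve a [roc_auc()] result.
#' @param n_pos,n_neg class sizes (default: taken from the curve).
#' @return An object of class `operating_point`: `threshold`,
#'   `sensitivity`, `specificity`, `accuracy`, `balanced_accuracy`.
#' @export
operating_point <- function(curve, n_pos = curve$n_pos,
                            n_neg = curve$n_neg) {
  bacc <- (curve$tpr + (1 - curve$fpr)) / 2
  cand <- which(bacc >= max(bacc) - 1e-12)
  best <- cand[which.min(curve$fpr[cand])]
  sens <- curve$tpr[best]
  spec <- 1 - curve$fpr[best]
  structure(
    list(threshold = curve$thresholds[best], sensitivity = sens,
         specificity = spec,
         accuracy = (sens * n_pos + spec * n_neg) / (n_pos + n_neg),
         balanced_accuracy = bacc[best]),
    class = "operating_point"
  )
}

# Constructor shared by every inferential procedure. Resampling p-values
# use the (b + 1)/(B + 1) convention, so they are never exactly 0.
test_result <- function(method, statistic, p_value, n_resamples = NA,
                        sidedness = "two_sided", adjustment = "none",
                        seed = NA, extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, p_value = p_value,
           n_resamples = n_resamples, sidedness = sidedness,
           adjustment = adjustment, seed = seed), extra),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, p = %.4g (%s, %s)\n",
              x$method, x$statistic, x$p_value, x$sidedness, x$adjustment))
  invisible(x)
}

#' Bootstrap percentile test for paired AUCs
#'
#' Compares the AUCs of two score vectors computed on the same subjects by
#' stratified resampling of subjects with replacement (cases and controls
#' separately). The p-value locates 0 in the percentile distribution of
#' the resampled AUC difference, with the (b+1)/(B+1) convention.
#'
#' @param scores_1,scores_2 paired score vectors on identical subjects.
#' @param labels binary case labels.
#' @param n_boot bootstrap resamples (default 5000).
#' @param sidedness `"two_sided"` (default), `"greater"` or `"less"`,
#'   referring to `AUC_1 - AUC_2`.
#' @param seed resampling seed.
#' @return A `test_result`; `statistic` is the observed AUC difference.
#' @export
bootstrap_paired_auc_test <- function(scores_1, scores_2, labels,
                                      n_boot = 5000,
                                      sidedness = "two_sided", seed = 1) {
  positive <- as.logical(labels)
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(positive)) {
    stop("paired scores and labels must have equal length", call. = FALSE)
  }
  obs <- auc_rank(scores_1, positive) - auc_rank(scores_2, positive)
  pos_idx <- which(positive)
  neg_idx <- which(!positive)
  set.seed(seed)
  delta <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos_idx, replace = TRUE),
             sample(neg_idx, replace = TRUE))
    pos_b <- positive[idx]
    auc_rank(scores_1[idx], pos_b) - auc_rank(scores_2[idx], pos_b)
  }, numeric(1))
  p_le <- (sum(delta <= 0) + 1) / (n_boot + 1)
  p_ge <- (sum(delta >= 0) + 1) / (n_boot + 1)
  p <- switch(sidedness,
              two_sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_le,   # small when 0 sits below the distribution
              less = p_ge,
              stop("unknown sidedness: ", sidedness, call. = FALSE))
  test_result("bootstrap_paired_auc", obs, p, n_boot, sidedness,
              seed = seed, extra = list(delta_quantiles = stats::quantile(
                delta, c(0.025, 0.5, 0.975))))
}

#' Permutation tests against chance with max-statistic FWE correction
#'
#' Tests each model's AUC against the chance level by permuting the labels
#' (scores held fixed). All models are evaluated on the same permutation,
#' and each model's family-wise adjusted p-value compares its observed AUC
#' with the permutation distribution of the maximum AUC across models.
#'
#' @param score_sets named list of score vectors on identical subjects.
#' @param labels binary case labels.
#' @param n_perm permutations (default 5000).
#' @param seed permutation seed.
#' @return Named list of `test_result`s with `adjustment =
#'   "max_statistic"`; each carries the unadjusted p as `p_unadjusted`.
#' @export
permutation_vs_chance <- function(score_sets, labels, n_perm = 5000,
                                  seed = 1) {
  positive <- as.logical(labels)
  lens <- lengths(score_sets)
  if (any(lens != length(positive))) {
    stop("all score sets must cover the same subjects", call. = FALSE)
  }
  obs <- vapply(score_sets, auc_rank, numeric(1), positive = positive)
  set.seed(seed)
  perm_auc <- matrix(NA_real_, n_perm, length(score_sets))
  for (b in seq_len(n_perm)) {
    perm <- sample(positive)
    perm_auc[b, ] <- vapply(score_sets, auc_rank, numeric(1),
                            positive = perm)
  }
  perm_max <- apply(perm_auc, 1, max)
  out <- lapply(seq_along(score_sets), function(m) {
    p_adj <- (sum(perm_max >= obs[m]) + 1) / (n_perm + 1)
    p_un <- (sum(perm_auc[, m] >= obs[m]) + 1) / (n_perm + 1)
    test_result("permutation_vs_chance", obs[m], p_adj, n_perm,
                sidedness = "greater", adjustment = "max_statistic",
                seed = seed, extra = list(p_unadjusted = p_un))
  })
  stats::setNames(out, names(score_sets))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of all group assignments (on midranks, so ties are
#' handled) when both groups have at most 10 observations; otherwise the
#' tie-corrected normal approximation.
#'
#' @param group_a,group_b numeric score vectors.
#' @return A `test_result`; `statistic` is the rank-sum of `group_a`.
#' @export
ranksum_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled, ties.method = "average")
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  if (n1 <= 10 && n2 <= 10) {
    combos <- utils::combn(n1 + n2, n1)
    ws <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    method <- "wilcoxon_ranksum_exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "wilcoxon_ranksum_normal"
  }
  test_result(method, w, min(1, p), sidedness = "two_sided")
}

#' Offset-correct probability scores
#'
#' Subtracts the global minimum so the smallest score is exactly 0. A
#' monotone shift: ranks, AUCs and rank tests are unchanged.
#'
#' @param scores numeric vector.
#' @return Shifted vector with minimum 0.
#' @export
offset_correct <- function(scores) {
  if (length(scores) == 0) stop("empty score vector", call. = FALSE)
  scores - min(scores)
}

#' Overlap of case and control score distributions
#'
#' `O = 1 - |2 AUC - 1|`: 1 when the distributions are indistinguishable
#' (AUC 0.5), 0 at perfect separation in either direction. Rank-based, so
#' insensitive to the differing probability scales of different models.
#'
#' @param scores numeric score vector.
#' @param labels binary case labels.
#' @return Scalar in \[0, 1\].
#' @export
overlap_statistic <- function(scores, labels) {
  1 - abs(2 * auc_rank(scores, as.logical(labels)) - 1)
}

#' Permutation test comparing score overlap between two settings
#'
#' Tests whether the case/control score overlap of one (scores, labels)
#' collection exceeds that of another. The null pools the subjects of both
#' collections stratified by label and randomly reassigns them to two sets
#' of the original sizes; the observed overlap difference is located in
#' the permutation distribution with the (b+1)/(B+1) convention.
#'
#' @param scores_1,labels_1 first collection.
#' @param scores_2,labels_2 second collection.
#' @param n_perm permutations (default 5000).
#' @param sidedness `"greater"` (default; overlap of set 1 exceeds set 2)
#'   or `"two_sided"`.
#' @param n_comparisons Bonferroni family size (default 1 = no adjustment).
#' @param seed permutation seed.
#' @return A `test_result`; `statistic` is the observed overlap difference
#'   `O_1 - O_2`; `p_value` is Bonferroni-adjusted when
#'   `n_comparisons > 1` (raw p kept as `p_unadjusted`).
#' @export
overlap_permutation_test <- function(scores_1, labels_1, scores_2, labels_2,
                                     n_perm = 5000, sidedness = "greater",
                                     n_comparisons = 1, seed = 1) {
  l1 <- as.logical(labels_1)
  l2 <- as.logical(labels_2)
  obs <- overlap_statistic(scores_1, l1) - overlap_statistic(scores_2, l2)
  pos_pool <- c(scores_1[l1], scores_2[l2])
  neg_pool <- c(scores_1[!l1], scores_2[!l2])
  n_pos1 <- sum(l1)
  n_neg1 <- sum(!l1)
  if (n_pos1 == 0 || n_neg1 == 0 || sum(l2) == 0 || sum(!l2) == 0) {
    stop("each collection needs both classes for a stratified ",
         "reassignment", call. = FALSE)
  }
  set.seed(seed)
  delta <- vapply(seq_len(n_perm), function(b) {
    pos_perm <- sample(pos_pool)
    neg_perm <- sample(neg_pool)
    s1 <- c(pos_perm[seq_len(n_pos1)], neg_perm[seq_len(n_neg1)])
    p1 <- c(rep(TRUE, n_pos1), rep(FALSE, n_neg1))
    s2 <- c(pos_perm[-seq_len(n_pos1)], neg_perm[-seq_len(n_neg1)])
    p2 <- c(rep(TRUE, length(pos_pool) - n_pos1),
            rep(FALSE, length(neg_pool) - n_neg1))
    overlap_statistic(s1, p1) - overlap_statistic(s2, p2)
  }, numeric(1))
  p_raw <- switch(sidedness,
                  greater = (sum(delta >= obs) + 1) / (n_perm + 1),
                  two_sided = min(1, 2 * min(
                    (sum(delta >= obs) + 1) / (n_perm + 1),
                    (sum(delta <= obs) + 1) / (n_perm + 1))),
                  stop("unknown sidedness: ", sidedness, call. = FALSE))
  p_adj <- min(1, p_raw * n_comparisons)
  test_result("overlap_permutation", obs, p_adj, n_perm, sidedness,
              adjustment = if (n_comparisons > 1) "bonferroni" else "none",
              seed = seed, extra = list(p_unadjusted = p_raw,
                                        n_comparisons = n_comparisons))
}
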