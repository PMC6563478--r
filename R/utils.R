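# Internal helpers shared across modules.

# Deterministic seed derivation: one master seed drives a named stream of
# sub-seeds so that, e.g., the affected-feature pattern does not change when
# only the noise stream is re-drawn at a different sample size. Polynomial
# string hash folded into [1, 2^31 - 19); all arithmetic stays below 2^53.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h %% 2147483629 + 1)
}

# Mann-Whitney AUC via midranks; ties get half credit. `positive` logical.
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: every class is spread as evenly as possible
# over k folds. Errors when a class is too small to reach every fold.
stratified_folds <- function(positive, k) {
  n <- length(positive)
  fold <- integer(n)
  for (cls in unique(positive)) {
    idx <- which(positive == cls)
    if (length(idx) < k) {
      stop(sprintf(
        "stratification infeasible: class '%s' has %d subjects for %d folds",
        cls, length(idx), k
      ), call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
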