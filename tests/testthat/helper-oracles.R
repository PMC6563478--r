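# Independent oracles and small fixture builders used across test files.

# Pair-counting AUC by exhaustive enumeration of all case-control pairs,
# half credit for ties. Quadratic; for small n only.
brute_force_auc <- function(scores, positive) {
  pos <- scores[as.logical(positive)]
  neg <- scores[!as.logical(positive)]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Optimal operating point by exhaustive sweep over all candidate
# thresholds (midpoints between consecutive sorted scores plus the
# extremes), maximizing balanced accuracy; ties toward higher specificity.
brute_force_operating_point <- function(scores, positive) {
  positive <- as.logical(positive)
  s <- sort(unique(scores))
  cand <- c(min(s) - 1, (head(s, -1) + tail(s, -1)) / 2, s, max(s) + 1)
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[positive] >= t)
    spec <- mean(scores[!positive] < t)
    bacc <- (sens + spec) / 2
    if (is.null(best) || bacc > best$bacc + 1e-12 ||
        (abs(bacc - best$bacc) <= 1e-12 && spec > best$spec)) {
      best <- list(bacc = bacc, sens = sens, spec = spec)
    }
  }
  best
}

# Tiny three-subject cohort-A table with hand-set values.
toy_table <- function() {
  subjects <- data.frame(
    subject_id = c("A_1", "A_2", "A_3"), cohort = "A",
    group = c("control", "control", "mild_ad"),
    age = c(65, 70, 72), sex = c(0, 1, 1)
  )
  values <- matrix(c(1.25, -0.5, 3.75,
                     0.125, 2.5, -1.5), 3, 2,
                   dimnames = list(NULL, c("GMD_001", "FA_001")))
  feature_table(subjects, values)
}

# Small generator configuration for fast module tests; any sim_config
# argument can be overridden.
small_config <- function(...) {
  defaults <- list(
    group_sizes = list(
      A = c(control = 60, mild_ad = 20, moderate_ad = 20),
      B = c(control = 80, mci_amnestic = 10, mci_nonamnestic = 10)),
    n_features_per_block = c(GMD = 20, DGMV = 6, WMD = 8, FA = 8, MD = 8))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
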