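#' Configuration of the two-cohort synthetic study
#'
#' Collects the data-generating assumptions the downstream analysis relies
#' on: group sizes of a clinical cohort A (controls, mild and moderate AD)
#' and a population cohort B (controls, amnestic and nonamnestic MCI), a
#' disease-severity continuum expressed as multiples of a base effect on a
#' seeded subset of features, an affine per-feature scanner distortion for
#' cohort B, and linear age/sex covariate effects. Features are modelled in
#' standardized units (baseline ~ N(0, 1), residual noise `noise_sd`).
#'
#' Defaults reproduce the study conditions of the cross-cohort design the
#' package implements: 173/39/38 subjects in cohort A, 617/23/25 in cohort
#' B, a scanner effect of slope 1.2 and offset 0.5 on cohort B, and a
#' moderate-AD pattern sharing `pattern_divergence` of its affected
#' features with the mild-AD pattern. Both MCI subtypes express the
#' mild-AD pattern attenuated by their severity multiplier.
#'
#' @param group_sizes named list with elements `A` and `B`, each a named
#'   count vector over the cohort's diagnostic groups.
#' @param n_features_per_block named counts per measure block.
#' @param affected_fraction fraction of features per block carrying disease
#'   signal.
#' @param effect_size_base standardized mean shift (units of `noise_sd`)
#'   for mild AD on affected features.
#' @param severity_multipliers named multipliers of `effect_size_base` per
#'   group; `control` must be 0.
#' @param pattern_divergence rho in \[0, 1\]: fraction of the moderate-AD
#'   affected set shared with the mild-AD set (1 = identical patterns).
#' @param scanner_slope,scanner_offset affine distortion applied to cohort
#'   B feature values (scalar or per-feature vector).
#' @param age_range named list `A`/`B` of (min, max) uniform age ranges.
#' @param age_slope,sex_offset linear covariate effects on every feature.
#' @param noise_sd residual standard deviation (> 0).
#' @param seed master seed; all randomness is derived from it by named
#'   sub-streams so the affected pattern is invariant to sample sizes.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(group_sizes = list(
                         A = c(control = 173, mild_ad = 39, moderate_ad = 38),
                         B = c(control = 617, mci_amnestic = 23,
                               mci_nonamnestic = 25)),
                       n_features_per_block = c(GMD = 96, DGMV = 14,
                                                WMD = 20, FA = 20, MD = 20),
                       affected_fraction = 0.2,
                       effect_size_base = 0.5,
                       severity_multipliers = c(control = 0,
                                                mci_amnestic = 0.3,
                                                mci_nonamnestic = 0.3,
                                                mild_ad = 1,
                                                moderate_ad = 1.25),
                       pattern_divergence = 0.3,
                       scanner_slope = 1.2,
                       scanner_offset = 0.5,
                       age_range = list(A = c(49, 84), B = c(57, 78)),
                       age_slope = -0.02,
                       sex_offset = 0.1,
                       noise_sd = 1,
                       seed = 1L) {
  config <- structure(
    list(group_sizes = group_sizes,
         n_features_per_block = n_features_per_block,
         affected_fraction = affected_fraction,
         effect_size_base = effect_size_base,
         severity_multipliers = severity_multipliers,
         pattern_divergence = pattern_divergence,
         scanner_slope = scanner_slope,
         scanner_offset = scanner_offset,
         age_range = age_range,
         age_slope = age_slope,
         sex_offset = sex_offset,
         noise_sd = noise_sd,
         seed = seed),
    class = "sim_config"
  )
  validate_sim_config(config)
}

validate_sim_config <- function(config) {
  cfg_stop <- function(field, msg) {
    stop(sprintf("invalid simulation configuration: field '%s' %s",
                 field, msg), call. = FALSE)
  }
  gs <- config$group_sizes
  if (!is.list(gs) || !all(c("A", "B") %in% names(gs))) {
    cfg_stop("group_sizes", "must be a list with elements 'A' and 'B'")
  }
  if (length(setdiff(names(gs$A), GROUPS_A)) > 0) {
    cfg_stop("group_sizes", paste("cohort A admits only groups",
                                  paste(GROUPS_A, collapse = ", ")))
  }
  if (length(setdiff(names(gs$B), GROUPS_B)) > 0) {
    cfg_stop("group_sizes", paste("cohort B admits only groups",
                                  paste(GROUPS_B, collapse = ", ")))
  }
  if (any(unlist(gs) < 0) || any(unlist(gs) != round(unlist(gs)))) {
    cfg_stop("group_sizes", "counts must be nonnegative integers")
  }
  nf <- config$n_features_per_block
  if (!all(names(nf) %in% MEASURE_BLOCKS) || any(nf < 0)) {
    cfg_stop("n_features_per_block",
             "must be nonnegative counts over known measure blocks")
  }
  if (config$affected_fraction < 0 || config$affected_fraction > 1) {
    cfg_stop("affected_fraction", "must lie in [0, 1]")
  }
  sm <- config$severity_multipliers
  if (is.na(sm["control"]) || sm["control"] != 0) {
    cfg_stop("severity_multipliers", "must map 'control' to 0")
  }
  if (any(sm < 0)) cfg_stop("severity_multipliers", "must be nonnegative")
  if (config$pattern_divergence < 0 || config$pattern_divergence > 1) {
    cfg_stop("pattern_divergence", "must lie in [0, 1]")
  }
  if (config$noise_sd <= 0) cfg_stop("noise_sd", "must be positive")
  if (any(config$scanner_slope == 0)) {
    cfg_stop("scanner_slope", "must be nonzero")
  }
  for (ch in c("A", "B")) {
    rg <- config$age_range[[ch]]
    if (length(rg) != 2 || rg[2] < rg[1]) {
      cfg_stop("age_range", sprintf("cohort %s range must be (min, max)", ch))
    }
  }
  config
}

# Signed affected-feature patterns. The mild pattern (shared by both MCI
# subtypes) picks round(affected_fraction * n_b) features per block; the
# moderate pattern keeps a fraction `rho` of those per block and draws the
# remainder from the block's unaffected features, so pattern overlap is
# controlled independently of pattern size.
draw_patterns <- function(config, feature_ids, blocks) {
  set.seed(derive_seed(config$seed, "pattern"))
  p <- length(feature_ids)
  mild <- stats::setNames(numeric(p), feature_ids)
  moderate <- stats::setNames(numeric(p), feature_ids)
  rho <- config$pattern_divergence
  for (b in names(config$n_features_per_block)) {
    ids <- names(blocks)[blocks == b]
    k <- round(config$affected_fraction * length(ids))
    if (k == 0) next
    aff_mild <- sample(ids, k)
    signs <- sample(c(-1, 1), k, replace = TRUE)
    mild[aff_mild] <- signs
    n_shared <- round(rho * k)
    shared <- if (n_shared > 0) sample(aff_mild, n_shared) else character(0)
    pool <- setdiff(ids, aff_mild)
    n_new <- min(k - n_shared, length(pool))
    fresh <- if (n_new > 0) sample(pool, n_new) else character(0)
    moderate[shared] <- mild[shared]
    moderate[fresh] <- sample(c(-1, 1), length(fresh), replace = TRUE)
  }
  list(mild = mild, moderate = moderate)
}

#' Generate the two synthetic cohorts
#'
#' Draws subject covariates and feature values under the model
#' `value = baseline + multiplier * effect_size_base * pattern +
#' age_slope * (age - center) + sex_offset * sex + noise`, then passes
#' cohort B through the scanner affine
#' `value * scanner_slope + scanner_offset`. Mild-AD and both MCI groups
#' express the mild pattern; moderate AD expresses its own pattern sharing
#' `pattern_divergence` of the affected features. Deterministic given the
#' configured seed.
#'
#' @param config a [sim_config()].
#' @return A list of class `cohort_pair` with elements `a` and `b` (two
#'   [feature_table()]s), `truth` (signed patterns, baselines, age center)
#'   and `config`.
#' @export
generate_cohorts <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  nf <- config$n_features_per_block
  feature_ids <- unlist(lapply(names(nf), function(b) {
    if (nf[[b]] == 0) return(character(0))
    sprintf("%s_%03d", b, seq_len(nf[[b]]))
  }), use.names = FALSE)
  blocks <- feature_block_of(feature_ids)
  p <- length(feature_ids)

  patterns <- draw_patterns(config, feature_ids, blocks)
  set.seed(derive_seed(config$seed, "baseline"))
  baseline <- stats::setNames(stats::rnorm(p), feature_ids)
  age_center <- mean(c(mean(config$age_range$A), mean(config$age_range$B)))

  make_cohort <- function(cohort) {
    sizes <- config$group_sizes[[cohort]]
    sizes <- sizes[sizes > 0]
    groups <- rep(names(sizes), times = sizes)
    n <- length(groups)
    subjects <- data.frame(
      subject_id = sprintf("%s_%04d", cohort, seq_len(n)),
      cohort = cohort,
      group = groups,
      stringsAsFactors = FALSE
    )
    set.seed(derive_seed(config$seed, "covariates", cohort))
    rg <- config$age_range[[cohort]]
    subjects$age <- stats::runif(n, rg[1], rg[2])
    subjects$sex <- stats::rbinom(n, 1, 0.5)

    pattern_of <- function(group) {
      if (group == "moderate_ad") patterns$moderate else patterns$mild
    }
    mult <- config$severity_multipliers
    signal <- t(vapply(groups, function(g) {
      mult[[g]] * config$effect_size_base * config$noise_sd * pattern_of(g)
    }, numeric(p)))
    set.seed(derive_seed(config$seed, "noise", cohort))
    noise <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
    values <- matrix(baseline, n, p, byrow = TRUE) + signal +
      config$age_slope * (subjects$age - age_center) +
      config$sex_offset * subjects$sex + noise
    colnames(values) <- feature_ids
    if (cohort == "B") {
      slope <- rep_len(config$scanner_slope, p)
      offset <- rep_len(config$scanner_offset, p)
      values <- sweep(sweep(values, 2, slope, "*"), 2, offset, "+")
    }
    feature_table(subjects, values)
  }

  structure(
    list(a = make_cohort("A"), b = make_cohort("B"),
         truth = list(pattern_mild = patterns$mild,
                      pattern_moderate = patterns$moderate,
                      baseline = baseline, age_center = age_center),
         config = config),
    class = "cohort_pair"
  )
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat("<cohort_pair>\n")
  print(x$a)
  print(x$b)
  invisible(x)
}

#' Oracle linear score
#'
#' Dot product of each subject's feature vector with a fixed weight vector
#' (typically a true generating pattern). Used as a model-free reference
#' score when probing the generator and the center correction.
#'
#' @param table a [feature_table()].
#' @param weights named numeric vector over (a subset of) feature ids.
#' @return Numeric score per subject.
#' @export
oracle_score <- function(table, weights) {
  ids <- names(weights)
  missing_ids <- setdiff(ids, colnames(table$values))
  if (length(missing_ids) > 0) {
    stop("weights refer to unknown features: ",
         paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  drop(table$values[, ids, drop = FALSE] %*% weights)
}
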