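#' Configuration of a full cross-cohort study
#'
#' Bundles the simulation settings with the harmonization, classification
#' and evaluation settings of the four study arms. `profile = "paper"`
#' uses the full 100-repetition protocol with the complete hyperparameter
#' grid; `profile = "test"` is the desk-scale variant (10 repetitions, a
#' 3-point alpha grid, 1000 resamples) that preserves the design while
#' fitting interactive runtimes.
#'
#' @param simulation a [sim_config()]; its seed is overridden by a stream
#'   derived from `seed` unless `keep_sim_seed = TRUE`.
#' @param profile `"paper"` or `"test"`.
#' @param repetitions repetitions of the train/correct/score cycle (and of
#'   the MCI-arm cross-validation). Defaults by profile (100 / 10).
#' @param selection_repetitions nested-CV repetitions per candidate during
#'   measure-set selection (defaults 2 / 1).
#' @param reselect_each_repetition re-run measure-set selection inside
#'   every repetition instead of fixing it upfront (default `FALSE`).
#' @param n_match,n_draws center-correction settings (68 controls per
#'   cohort, 5 draws).
#' @param k_outer,k_inner fold counts (10/10).
#' @param alpha_grid,nlambda,lambda_min_ratio hyperparameter grid.
#' @param n_boot,n_perm resamples for the evaluation battery.
#' @param measure_sets candidate measure sets for selection.
#' @param seed master seed; every stage derives named sub-seeds from it.
#' @param keep_sim_seed keep the seed already inside `simulation`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(simulation = sim_config(),
                              profile = c("paper", "test"),
                              repetitions = NULL,
                              selection_repetitions = NULL,
                              reselect_each_repetition = FALSE,
                              n_match = 68, n_draws = 5,
                              k_outer = 10, k_inner = 10,
                              alpha_grid = NULL, nlambda = NULL,
                              lambda_min_ratio = 1e-4,
                              n_boot = NULL, n_perm = NULL,
                              measure_sets = c("multiparametric",
                                               MEASURE_BLOCKS),
                              seed = 1, keep_sim_seed = FALSE) {
  profile <- match.arg(profile)
  test <- profile == "test"
  repetitions <- repetitions %||% if (test) 10 else 100
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  selection_repetitions <- selection_repetitions %||% if (test) 1 else 2
  alpha_grid <- alpha_grid %||%
    if (test) c(0.1, 0.5, 1) else seq(0.1, 1, by = 0.1)
  nlambda <- nlambda %||% if (test) 30 else 50
  n_boot <- n_boot %||% if (test) 1000 else 5000
  n_perm <- n_perm %||% if (test) 1000 else 5000
  if (!keep_sim_seed) simulation$seed <- derive_seed(seed, "simulate")
  structure(
    list(simulation = simulation, profile = profile,
         repetitions = repetitions,
         selection_repetitions = selection_repetitions,
         reselect_each_repetition = reselect_each_repetition,
         n_match = n_match, n_draws = n_draws,
         k_outer = k_outer, k_inner = k_inner,
         alpha_grid = alpha_grid, nlambda = nlambda,
         lambda_min_ratio = lambda_min_ratio,
         n_boot = n_boot, n_perm = n_perm,
         measure_sets = measure_sets, seed = seed),
    class = "experiment_config"
  )
}

arm_positive_groups <- function(arm) {
  switch(arm,
         ad = c("mild_ad", "moderate_ad"),
         mild_ad = "mild_ad",
         moderate_ad = "moderate_ad",
         mci = c("mci_amnestic", "mci_nonamnestic"),
         stop("unknown arm: ", arm, call. = FALSE))
}

# Measure-set selection by repeated nested CV over the configured
# candidates, on the training table of an arm. Returns the selection table
# and the multiparametric cv_result (the within-training-cohort reference
# performance used by the evaluation stage).
run_measure_selection <- function(table, positive_groups, config, seed) {
  results <- lapply(stats::setNames(config$measure_sets,
                                    config$measure_sets), function(ms) {
    nested_cv(table, positive_groups, measure_set = ms,
              k_outer = config$k_outer, k_inner = config$k_inner,
              repetitions = config$selection_repetitions,
              alpha_grid = config$alpha_grid, nlambda = config$nlambda,
              lambda_min_ratio = config$lambda_min_ratio,
              seed = derive_seed(seed, "select", ms))
  })
  sel <- select_measure_set(results)
  list(chosen = sel$chosen, table = sel$table,
       within_cv = results[["multiparametric"]] %||% results[[sel$chosen]])
}

#' Run a transfer arm of the study
#'
#' Trains the arm's classifier on cohort A (controls plus the arm's
#' patient subset), harmonizes cohort B into cohort-A feature space with a
#' fresh correction ensemble per repetition, and scores every cohort-B
#' subject. Measure-set selection runs once upfront (configurable to run
#' per repetition). Training never sees a cohort-B label; the AUC summary
#' is computed afterwards from the returned scores.
#'
#' @param arm `"ad"`, `"mild_ad"` or `"moderate_ad"`.
#' @param cohort_a,cohort_b the two [feature_table()]s.
#' @param config an [experiment_config()].
#' @return An object of class `arm_result`: per-repetition cohort-B score
#'   matrix, chosen measure set, selection table, within-cohort-A
#'   `cv_result`, per-repetition hyperparameters, and an AUC summary row.
#' @export
run_transfer_arm <- function(arm, cohort_a, cohort_b, config) {
  positive_groups <- arm_positive_groups(arm)
  keep <- cohort_a$subjects$group %in% c("control", positive_groups)
  if (!any(cohort_a$subjects$group %in% positive_groups)) {
    stop("arm '", arm, "' has no patients in cohort A", call. = FALSE)
  }
  train_table <- ft_subset(cohort_a, keep)
  seed <- derive_seed(config$seed, "arm", arm)
  selection <- run_measure_selection(train_table, positive_groups, config,
                                     seed)
  n_b <- nrow(cohort_b$values)
  scores <- matrix(NA_real_, n_b, config$repetitions,
                   dimnames = list(cohort_b$subjects$subject_id, NULL))
  params <- vector("list", config$repetitions)
  chosen <- selection$chosen
  for (r in seq_len(config$repetitions)) {
    if (config$reselect_each_repetition && r > 1) {
      selection_r <- run_measure_selection(train_table, positive_groups,
                                           config,
                                           derive_seed(seed, "resel", r))
      chosen <- selection_r$chosen
    }
    ensemble <- build_correction_ensemble(
      cohort_a, cohort_b, n_draws = config$n_draws,
      n_match = config$n_match, seed = derive_seed(seed, "correct", r))
    corrected_b <- correct_cohort(ensemble, cohort_b)
    model <- train_classifier(
      train_table, positive_groups, measure_set = chosen,
      alpha_grid = config$alpha_grid, k_inner = config$k_inner,
      nlambda = config$nlambda,
      lambda_min_ratio = config$lambda_min_ratio,
      seed = derive_seed(seed, "train", r))
    scores[, r] <- score_table(model, corrected_b)
    params[[r]] <- data.frame(repetition = r, alpha = model$alpha,
                              lambda = model$lambda, measure_set = chosen)
  }
  res <- structure(
    list(arm = arm, scores = scores, subjects = cohort_b$subjects,
         measure_set = chosen, selection_table = selection$table,
         within_cv = selection$within_cv,
         chosen_params = do.call(rbind, params)),
    class = "arm_result"
  )
  res$summary <- summarize_arm(res)
  res
}

#' Run the within-cohort-B cross-validated arm
#'
#' The MCI arm never leaves cohort B: measure-set selection and the
#' repeated nested cross-validation both run on cohort B, and each
#' subject's score is its out-of-fold prediction. No harmonization stage.
#'
#' @param cohort_b the population [feature_table()].
#' @param config an [experiment_config()].
#' @return An `arm_result` whose score matrix holds the out-of-fold
#'   probability scores per repetition; `within_cv` is the full
#'   [nested_cv()] result.
#' @export
run_mci_arm <- function(cohort_b, config) {
  positive_groups <- arm_positive_groups("mci")
  seed <- derive_seed(config$seed, "arm", "mci")
  selection <- run_measure_selection(cohort_b, positive_groups, config,
                                     seed)
  cv <- nested_cv(cohort_b, positive_groups,
                  measure_set = selection$chosen,
                  k_outer = config$k_outer, k_inner = config$k_inner,
                  repetitions = config$repetitions,
                  alpha_grid = config$alpha_grid, nlambda = config$nlambda,
                  lambda_min_ratio = config$lambda_min_ratio,
                  seed = derive_seed(seed, "cv"))
  res <- structure(
    list(arm = "mci", scores = cv$oof_scores, subjects = cohort_b$subjects,
         measure_set = selection$chosen,
         selection_table = selection$table, within_cv = selection$within_cv,
         cv_result = cv,
         chosen_params = cv$chosen_params),
    class = "arm_result"
  )
  res$summary <- summarize_arm(res)
  res
}

# Per-repetition ROC of an arm's cohort-B scores against the MCI labels:
# mean/min/max AUC plus the mean operating-point measures.
summarize_arm <- function(res) {
  positive <- res$subjects$group != "control"
  reps <- ncol(res$scores)
  aucs <- numeric(reps)
  sens <- spec <- acc <- numeric(reps)
  for (r in seq_len(reps)) {
    curve <- roc_auc(res$scores[, r], positive)
    op <- operating_point(curve)
    aucs[r] <- curve$auc
    sens[r] <- op$sensitivity
    spec[r] <- op$specificity
    acc[r] <- op$accuracy
  }
  data.frame(
    model = res$arm, measure = res$measure_set,
    auc = mean(aucs), auc_min = min(aucs), auc_max = max(aucs),
    sensitivity = mean(sens), specificity = mean(spec),
    accuracy = mean(acc), repetitions = reps
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf(
    "<arm_result> %s (%s): mean AUC %.3f [%.3f-%.3f], %d repetitions\n",
    x$arm, x$measure_set, x$summary$auc, x$summary$auc_min,
    x$summary$auc_max, x$summary$repetitions))
  invisible(x)
}

#' Run the full inferential battery over the study arms
#'
#' Produces the performance table (mean/min/max AUC and mean operating
#' point per arm), pairwise paired-bootstrap AUC comparisons, permutation
#' tests against chance with max-statistic family-wise correction,
#' offset-corrected rank-sum score contrasts (case vs control and amnestic
#' vs nonamnestic), and Bonferroni-adjusted permutation comparisons of the
#' cohort-B score overlap against each arm's within-training-cohort
#' cross-validated overlap. Subject-level inference uses each subject's
#' mean score across repetitions.
#'
#' @param arms named list of `arm_result`s sharing cohort-B subjects.
#' @param config the [experiment_config()] of the run.
#' @return An object of class `study_evaluation` with elements
#'   `performance`, `pairwise_auc`, `vs_chance`, `score_contrasts`,
#'   `subtype_contrasts`, `overlap`.
#' @export
evaluate_study <- function(arms, config) {
  subj <- arms[[1]]$subjects
  for (a in arms) {
    if (!identical(a$subjects$subject_id, subj$subject_id)) {
      stop("arms disagree on cohort-B subjects", call. = FALSE)
    }
  }
  positive <- subj$group != "control"
  seed <- derive_seed(config$seed, "evaluate")
  mean_scores <- lapply(arms, function(a) rowMeans(a$scores))

  performance <- do.call(rbind, lapply(arms, `[[`, "summary"))
  rownames(performance) <- NULL

  pairs <- utils::combn(names(arms), 2)
  pairwise_auc <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a1 <- pairs[1, i]; a2 <- pairs[2, i]
    tr <- bootstrap_paired_auc_test(
      mean_scores[[a1]], mean_scores[[a2]], positive,
      n_boot = config$n_boot, seed = derive_seed(seed, "pair", a1, a2))
    data.frame(model_1 = a1, model_2 = a2, delta_auc = tr$statistic,
               p_value = tr$p_value, n_resamples = tr$n_resamples)
  }))

  chance <- permutation_vs_chance(mean_scores, positive,
                                  n_perm = config$n_perm,
                                  seed = derive_seed(seed, "chance"))
  vs_chance <- do.call(rbind, lapply(names(chance), function(m) {
    data.frame(model = m, auc = chance[[m]]$statistic,
               p_adjusted = chance[[m]]$p_value,
               p_unadjusted = chance[[m]]$p_unadjusted)
  }))

  score_contrasts <- do.call(rbind, lapply(names(arms), function(m) {
    sc <- offset_correct(mean_scores[[m]])
    tr <- ranksum_test(sc[positive], sc[!positive])
    data.frame(model = m, contrast = "case_vs_control",
               statistic = tr$statistic, p_value = tr$p_value)
  }))

  subtype_contrasts <- do.call(rbind, lapply(names(arms), function(m) {
    sc <- offset_correct(mean_scores[[m]])
    amn <- subj$group == "mci_amnestic"
    non <- subj$group == "mci_nonamnestic"
    if (!any(amn) || !any(non)) return(NULL)
    tr <- ranksum_test(sc[amn], sc[non])
    data.frame(model = m, contrast = "amnestic_vs_nonamnestic",
               statistic = tr$statistic, p_value = tr$p_value)
  }))

  # Reference: cross-validated scores within the arm's own training cohort
  # (the AD-cohort CV for the transfer arms; the AD arm's for the MCI arm,
  # which has no separate training cohort).
  overlap <- do.call(rbind, lapply(names(arms), function(m) {
    ref <- if (m == "mci" && "ad" %in% names(arms)) {
      arms[["ad"]]
    } else {
      arms[[m]]
    }
    ref_cv <- ref$within_cv
    ref_scores <- rowMeans(ref_cv$oof_scores)
    tr <- overlap_permutation_test(
      mean_scores[[m]], positive, ref_scores, ref_cv$labels == 1,
      n_perm = config$n_perm, sidedness = "greater",
      n_comparisons = length(arms),
      seed = derive_seed(seed, "overlap", m))
    data.frame(model = m, delta_overlap = tr$statistic,
               p_adjusted = tr$p_value, p_unadjusted = tr$p_unadjusted)
  }))

  structure(
    list(performance = performance, pairwise_auc = pairwise_auc,
         vs_chance = vs_chance, score_contrasts = score_contrasts,
         subtype_contrasts = subtype_contrasts, overlap = overlap,
         seed = seed),
    class = "study_evaluation"
  )
}

fmt_num <- function(x, d = 3) formatC(x, digits = d, format = "f")

#' Render a study report
#'
#' Markdown summary: the performance table (model, measure set, mean AUC,
#' min-max range, mean sensitivity/specificity/accuracy at the optimal
#' operating point) followed by the inferential tables. Deterministic
#' given its inputs; sections without results carry explicit "not run"
#' markers.
#'
#' @param evaluation a [evaluate_study()] result (or `NULL` sections).
#' @param config the [experiment_config()] used.
#' @param file optional path; when given the report is written there.
#' @return Character vector of markdown lines, invisibly when written.
#' @export
report <- function(evaluation, config, file = NULL) {
  lines <- c("# Cross-cohort MCI classification study", "",
             sprintf("Repetitions: %d (profile '%s'), master seed %d.",
                     config$repetitions, config$profile, config$seed), "",
             "## Classification performance", "")
  perf <- evaluation$performance
  if (is.null(perf) || nrow(perf) == 0) {
    lines <- c(lines, "_not run_")
  } else {
    lines <- c(lines,
      "| Model | Measure | AUC | Min-max | Sensitivity | Specificity | Accuracy |",
      "|---|---|---|---|---|---|---|",
      vapply(seq_len(nrow(perf)), function(i) {
        sprintf("| %s | %s | %s | %s-%s | %s | %s | %s |",
                perf$model[i], perf$measure[i], fmt_num(perf$auc[i]),
                fmt_num(perf$auc_min[i]), fmt_num(perf$auc_max[i]),
                fmt_num(perf$sensitivity[i]), fmt_num(perf$specificity[i]),
                fmt_num(perf$accuracy[i]))
      }, character(1)))
  }
  render_tests <- function(title, df, cols) {
    if (is.null(df) || nrow(df) == 0) {
      return(c("", paste("##", title), "", "_not run_"))
    }
    header <- paste0("| ", paste(cols, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|")
    rows <- vapply(seq_len(nrow(df)), function(i) {
      paste0("| ", paste(vapply(cols, function(cl) {
        v <- df[[cl]][i]
        if (is.numeric(v)) fmt_num(v, 4) else as.character(v)
      }, character(1)), collapse = " | "), " |")
    }, character(1))
    c("", paste("##", title), "", header, sep, rows)
  }
  lines <- c(lines,
    render_tests("Pairwise paired-bootstrap AUC comparisons",
                 evaluation$pairwise_auc,
                 c("model_1", "model_2", "delta_auc", "p_value")),
    render_tests("Permutation tests against chance (max-statistic FWE)",
                 evaluation$vs_chance,
                 c("model", "auc", "p_adjusted", "p_unadjusted")),
    render_tests("Offset-corrected score contrasts (rank-sum)",
                 evaluation$score_contrasts,
                 c("model", "contrast", "statistic", "p_value")),
    render_tests("Amnestic vs nonamnestic contrasts",
                 evaluation$subtype_contrasts,
                 c("model", "contrast", "statistic", "p_value")),
    render_tests("Score-overlap comparisons vs within-cohort CV (Bonferroni)",
                 evaluation$overlap,
                 c("model", "delta_overlap", "p_adjusted", "p_unadjusted")))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Run the complete four-arm study
#'
#' Generates (or accepts) the two cohorts, runs the three transfer arms
#' and the within-cohort MCI arm, evaluates everything, and renders the
#' report. Fully deterministic given the configuration's master seed.
#'
#' @param config an [experiment_config()].
#' @param cohorts optional pre-built [generate_cohorts()] result; by
#'   default cohorts are generated from `config$simulation`.
#' @param out_dir optional directory; when given, per-arm scores, the
#'   summary and test tables (CSV), the report (markdown) and a manifest
#'   (JSON) are written there.
#' @return An object of class `study_result` with `cohorts`, `arms`,
#'   `evaluation`, `report_lines` and `manifest`.
#' @export
run_study <- function(config = experiment_config(), cohorts = NULL,
                      out_dir = NULL) {
  cohorts <- cohorts %||% generate_cohorts(config$simulation)
  arms <- list(
    ad = run_transfer_arm("ad", cohorts$a, cohorts$b, config),
    mild_ad = run_transfer_arm("mild_ad", cohorts$a, cohorts$b, config),
    moderate_ad = run_transfer_arm("moderate_ad", cohorts$a, cohorts$b,
                                   config),
    mci = run_mci_arm(cohorts$b, config)
  )
  evaluation <- evaluate_study(arms, config)
  report_lines <- report(evaluation, config)
  config_echo <- config[setdiff(names(config), "simulation")]
  config_echo$simulation <- unclass(config$simulation)
  config_json <- jsonlite::toJSON(config_echo, auto_unbox = TRUE,
                                  digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mcitransfer")),
    seed = config$seed, profile = config$profile,
    repetitions = config$repetitions,
    config = config_echo,
    config_hash = derive_seed(0, config_json),
    arm_seeds = lapply(stats::setNames(names(arms), names(arms)),
                       function(a) derive_seed(config$seed, "arm", a)),
    repetition_seeds = lapply(
      stats::setNames(names(arms), names(arms)), function(a) {
        vapply(seq_len(config$repetitions), function(r) {
          derive_seed(derive_seed(config$seed, "arm", a), "train", r)
        }, integer(1))
      }),
    measure_sets = lapply(arms, `[[`, "measure_set")
  )
  res <- structure(
    list(cohorts = cohorts, arms = arms, evaluation = evaluation,
         report_lines = report_lines, manifest = manifest,
         config = config),
    class = "study_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (a in names(arms)) {
      utils::write.csv(
        data.frame(subject_id = rownames(arms[[a]]$scores),
                   arms[[a]]$scores, check.names = FALSE),
        file.path(out_dir, paste0("scores_", a, ".csv")),
        row.names = FALSE)
    }
    utils::write.csv(evaluation$performance,
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(evaluation$vs_chance,
                     file.path(out_dir, "tests_vs_chance.csv"),
                     row.names = FALSE)
    utils::write.csv(evaluation$pairwise_auc,
                     file.path(out_dir, "tests_pairwise_auc.csv"),
                     row.names = FALSE)
    writeLines(report_lines, file.path(out_dir, "report.md"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(x$evaluation$performance)
  invisible(x)
}
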