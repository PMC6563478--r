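#' Estimate per-feature linear center correction factors
#'
#' Draws a balanced set of `n_match` control subjects from each cohort and
#' matches, feature by feature, the mean and standard deviation of the
#' corrected cohort (B) to the training cohort (A):
#' `slope = sd_A / sd_B`, `intercept = mean_A - slope * mean_B`, both
#' computed on the sampled controls only. Applying the resulting map to the
#' sampled B controls reproduces the sampled A mean and SD exactly; the map
#' is intended for the subjects that were *not* used in estimation.
#'
#' Only control subjects inform the correction, so cohort differences are
#' attributed to hardware/protocol rather than disease.
#'
#' @param controls_a,controls_b [feature_table()]s (non-control rows are
#'   ignored) from the training cohort and the cohort to be corrected.
#' @param n_match controls sampled per cohort (default 68).
#' @param seed optional seed for the balanced draw.
#' @return An object of class `correction_model` with per-feature `slope`
#'   and `intercept`, the `estimation_ids` used per cohort, `n_match` and
#'   `direction = "B->A"`.
#' @export
estimate_correction <- function(controls_a, controls_b, n_match = 68,
                                seed = NULL) {
  controls_a <- ft_controls(controls_a)
  controls_b <- ft_controls(controls_b)
  if (!identical(colnames(controls_a$values), colnames(controls_b$values))) {
    stop("cohorts disagree on feature ids", call. = FALSE)
  }
  for (side in list(A = controls_a, B = controls_b)) {
    if (nrow(side$values) < n_match) {
      stop(sprintf(
        "need at least %d control subjects per cohort, got %d",
        n_match, nrow(side$values)), call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  ids_a <- sample(controls_a$subjects$subject_id, n_match)
  ids_b <- sample(controls_b$subjects$subject_id, n_match)
  va <- controls_a$values[ids_a, , drop = FALSE]
  vb <- controls_b$values[ids_b, , drop = FALSE]
  sd_a <- apply(va, 2, stats::sd)
  sd_b <- apply(vb, 2, stats::sd)
  if (any(sd_b == 0)) {
    stop("degenerate feature (zero variance in corrected cohort): ",
         colnames(vb)[which(sd_b == 0)[1]], call. = FALSE)
  }
  slope <- sd_a / sd_b
  intercept <- colMeans(va) - slope * colMeans(vb)
  structure(
    list(slope = slope, intercept = intercept,
         estimation_ids = list(A = sort(ids_a), B = sort(ids_b)),
         n_match = n_match, direction = "B->A"),
    class = "correction_model"
  )
}

#' Apply a center correction to a feature table
#'
#' @param model a [estimate_correction()] result.
#' @param table a [feature_table()] with the model's feature ids.
#' @return The table with `value * slope + intercept` per feature; labels
#'   and covariates untouched.
#' @export
apply_correction <- function(model, table) {
  if (!identical(colnames(table$values), names(model$slope))) {
    stop("feature ids of table and correction model do not match",
         call. = FALSE)
  }
  out <- table
  out$values <- sweep(sweep(table$values, 2, model$slope, "*"),
                      2, model$intercept, "+")
  out
}

#' Build an ensemble of center corrections covering every subject
#'
#' Repeats the balanced-control estimation `n_draws` times (default 5) so
#' that every cohort-B subject is left out of at least one estimation set
#' and can be corrected without using its own values. Draws that would
#' leave any subject uncovered are re-sampled.
#'
#' @param cohort_a,cohort_b [feature_table()]s of the training cohort and
#'   the cohort to be corrected.
#' @param n_draws number of repeated estimations (default 5).
#' @param n_match controls per cohort per draw (default 68).
#' @param seed seed driving all draws.
#' @return An object of class `correction_ensemble`: `draws` (list of
#'   `correction_model`) and `assignment` (per cohort-B subject id, the
#'   indices of draws usable for it).
#' @export
build_correction_ensemble <- function(cohort_a, cohort_b, n_draws = 5,
                                      n_match = 68, seed = NULL) {
  seed <- seed %||% derive_seed(0, "ensemble")
  all_b <- cohort_b$subjects$subject_id
  draws <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    draws[[d]] <- estimate_correction(cohort_a, cohort_b, n_match,
                                      seed = derive_seed(seed, "draw", d))
  }
  usable <- function(draws) {
    lapply(stats::setNames(all_b, all_b), function(id) {
      which(vapply(draws, function(m) !(id %in% m$estimation_ids$B),
                   logical(1)))
    })
  }
  assignment <- usable(draws)
  if (any(lengths(assignment) == 0)) {
    if (n_draws < 2) {
      stop("ensemble cannot cover all subjects with a single draw; ",
           "increase n_draws", call. = FALSE)
    }
    # Re-draw the last estimation set from the controls that the earlier
    # draws failed to leave out, guaranteeing full coverage in one step.
    uncovered_early <- names(which(lengths(usable(draws[-n_draws])) == 0))
    ctrl_b <- ft_controls(cohort_b)
    pool <- ft_subset(ctrl_b, !(ctrl_b$subjects$subject_id %in%
                                  uncovered_early))
    if (nrow(pool$values) < n_match) {
      stop("cannot cover all subjects: only ", nrow(pool$values),
           " controls available outside the uncovered set for a draw of ",
           n_match, call. = FALSE)
    }
    draws[[n_draws]] <- estimate_correction(
      cohort_a, pool, n_match, seed = derive_seed(seed, "redraw"))
    assignment <- usable(draws)
  }
  structure(
    list(draws = draws, assignment = assignment,
         n_draws = n_draws, n_match = n_match),
    class = "correction_ensemble"
  )
}

#' Serialize a correction ensemble to JSON
#'
#' Writes slopes, intercepts and estimation ids per draw, plus the
#' per-subject draw assignment, in a form [jsonlite::read_json()] can
#' round-trip.
#'
#' @param ensemble a [build_correction_ensemble()] result.
#' @param path destination JSON path.
#' @return Invisibly, `path`.
#' @export
write_correction_ensemble <- function(ensemble, path) {
  payload <- list(
    n_draws = ensemble$n_draws, n_match = ensemble$n_match,
    draws = lapply(ensemble$draws, function(d) {
      list(slope = as.list(d$slope), intercept = as.list(d$intercept),
           estimation_ids = d$estimation_ids, direction = d$direction)
    }),
    assignment = ensemble$assignment
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Correct a cohort with an ensemble of center corrections
#'
#' Each subject is corrected exactly once, using the average slope and
#' intercept over the draws whose estimation sets excluded it, so no
#' subject's corrected values depend on a map it helped estimate.
#'
#' @param ensemble a [build_correction_ensemble()] result.
#' @param cohort_b the [feature_table()] to correct.
#' @return The corrected `feature_table`.
#' @export
correct_cohort <- function(ensemble, cohort_b) {
  ids <- cohort_b$subjects$subject_id
  uncovered <- setdiff(ids, names(ensemble$assignment))
  if (length(uncovered) > 0) {
    stop("ensemble does not cover subject(s): ",
         paste(utils::head(uncovered, 3), collapse = ", "), call. = FALSE)
  }
  out <- cohort_b
  keys <- vapply(ensemble$assignment[ids],
                 function(ix) paste(ix, collapse = ","), character(1))
  for (key in unique(keys)) {
    ix <- ensemble$assignment[[ids[match(key, keys)]]]
    slope <- rowMeans(vapply(ensemble$draws[ix], `[[`, "slope",
                             FUN.VALUE = numeric(ncol(cohort_b$values))))
    intercept <- rowMeans(vapply(ensemble$draws[ix], `[[`, "intercept",
                                 FUN.VALUE = numeric(ncol(cohort_b$values))))
    rows <- which(keys == key)
    out$values[rows, ] <- sweep(
      sweep(cohort_b$values[rows, , drop = FALSE], 2, slope, "*"),
      2, intercept, "+")
  }
  out
}
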