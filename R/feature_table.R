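#' Measure blocks of the multiparametric feature set
#'
#' The five MRI measure families a feature can belong to: cortical gray
#' matter density (GMD), deep gray matter volume (DGMV), white matter
#' density (WMD), tract-averaged fractional anisotropy (FA) and mean
#' diffusivity (MD).
#'
#' @format Character vector of block names in their canonical order.
#' @export
MEASURE_BLOCKS <- c("GMD", "DGMV", "WMD", "FA", "MD")

VALID_GROUPS <- c("control", "mci_amnestic", "mci_nonamnestic",
                  "mild_ad", "moderate_ad")
GROUPS_A <- c("control", "mild_ad", "moderate_ad")
GROUPS_B <- c("control", "mci_amnestic", "mci_nonamnestic")

#' Construct a subjects-by-features table
#'
#' A `feature_table` couples a subject frame (id, cohort, diagnostic group,
#' age, sex) to a numeric feature matrix whose column names encode the
#' measure block (`GMD_001`, `FA_017`, ...). It is the common currency of
#' the generator, the center correction and the classifiers.
#'
#' @param subjects data.frame with columns `subject_id`, `cohort` (`"A"` or
#'   `"B"`), `group` (one of `control`, `mci_amnestic`, `mci_nonamnestic`,
#'   `mild_ad`, `moderate_ad`), `age` (years), `sex` (0/1).
#' @param values numeric matrix, one row per subject, column names are
#'   feature ids of the form `<BLOCK>_<index>`.
#' @return An object of class `feature_table` with elements `subjects`,
#'   `values` and `blocks` (named character vector feature id -> block).
#' @export
feature_table <- function(subjects, values) {
  required <- c("subject_id", "cohort", "group", "age", "sex")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols) > 0) {
    stop("subjects frame is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(values)
  if (nrow(values) != nrow(subjects)) {
    stop("row count of values (", nrow(values),
         ") does not match subject count (", nrow(subjects), ")",
         call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("feature matrix must carry feature ids as column names",
         call. = FALSE)
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("subject ids must be unique", call. = FALSE)
  }
  bad_group <- setdiff(unique(subjects$group), VALID_GROUPS)
  if (length(bad_group) > 0) {
    stop("unknown diagnostic group(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("feature matrix contains missing or non-finite values",
         call. = FALSE)
  }
  blocks <- feature_block_of(colnames(values))
  rownames(values) <- subjects$subject_id
  structure(
    list(subjects = as.data.frame(subjects, stringsAsFactors = FALSE),
         values = values, blocks = blocks),
    class = "feature_table"
  )
}

# Map feature ids to their measure block via the prefix before "_".
feature_block_of <- function(feature_ids) {
  prefix <- sub("_.*$", "", feature_ids)
  unknown <- setdiff(unique(prefix), MEASURE_BLOCKS)
  if (length(unknown) > 0) {
    stop("unknown measure-block prefix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(prefix, feature_ids)
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<feature_table> cohort %s: %d subjects x %d features\n",
              paste(unique(x$subjects$cohort), collapse = "/"),
              nrow(x$values), ncol(x$values)))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  blocks:", paste(sprintf("%s=%d", names(table(x$blocks)),
                                 table(x$blocks)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a feature table by subject
#'
#' @param table a [feature_table()].
#' @param idx logical or integer subject index.
#' @return A `feature_table` with the selected rows, order preserved.
#' @export
ft_subset <- function(table, idx) {
  feature_table(table$subjects[idx, , drop = FALSE],
                table$values[idx, , drop = FALSE])
}

#' Keep only control subjects
#' @param table a [feature_table()].
#' @return A `feature_table` restricted to `group == "control"`.
#' @export
ft_controls <- function(table) {
  ft_subset(table, table$subjects$group == "control")
}

# Feature-id columns belonging to a measure set ("multiparametric" = all).
measure_set_columns <- function(table, measure_set) {
  if (identical(measure_set, "multiparametric")) {
    return(colnames(table$values))
  }
  if (!measure_set %in% MEASURE_BLOCKS) {
    stop("unknown measure set: ", measure_set, call. = FALSE)
  }
  names(table$blocks)[table$blocks == measure_set]
}

#' Write a feature table to CSV
#'
#' One row per subject: `subject_id, cohort, group, age, sex` followed by
#' all feature columns. Values are written with 17 significant digits so a
#' write/read round trip reproduces doubles exactly.
#'
#' @param table a [feature_table()].
#' @param path destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  vals <- table$values
  chr <- matrix(formatC(vals, digits = 17, format = "g"),
                nrow = nrow(vals), dimnames = dimnames(vals))
  df <- cbind(
    table$subjects[, c("subject_id", "cohort", "group", "age", "sex")],
    as.data.frame(chr, stringsAsFactors = FALSE)
  )
  df$age <- formatC(table$subjects$age, digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Counterpart of [write_feature_table()]. The file must carry the subject
#' columns `subject_id, cohort, group, age, sex` and only feature columns
#' with a known measure-block prefix; any missing or non-numeric cell is a
#' parse error reporting its location.
#'
#' @param path CSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "cohort", "group", "age", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("feature-table file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  feat_cols <- setdiff(names(df), required)
  if (length(feat_cols) == 0) {
    stop("feature-table file contains no feature columns", call. = FALSE)
  }
  feature_block_of(feat_cols)  # errors on unknown prefixes
  vals <- as.matrix(df[, feat_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid numeric cell at row %d, column '%s'",
                 bad[1], feat_cols[bad[2]]), call. = FALSE)
  }
  feature_table(df[, required], vals)
}
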