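## Score ranges of the auditory-comprehension battery: yes/no questions and
## single-word recognition are scored 0-60, sequential commands 0-80, the
## overall comprehension score 0-10 (the subtest sum divided by 20), and the
## aphasia quotient 0-100.
score_ranges <- list(
  score_yesno = c(0, 60),
  score_word = c(0, 60),
  score_commands = c(0, 80),
  score_overall = c(0, 10),
  wab_aq = c(0, 100)
)

cohort_columns <- c("patient_id", "age", "gender", "education",
                    "months_post_stroke", "wab_aq", "lesion_volume_cc",
                    "score_yesno", "score_word", "score_commands",
                    "score_overall")

longitudinal_columns <- c("patient_id", "session_index", "months_post_onset",
                          "comprehension_score")

#' Read and validate a cross-sectional cohort table
#'
#' Expects a CSV with header and columns `patient_id`, `age`, `gender`
#' (`male`/`female`), `education`, `months_post_stroke`, `wab_aq`,
#' `lesion_volume_cc`, `score_yesno` (0-60), `score_word` (0-60),
#' `score_commands` (0-80), `score_overall` (0-10). Rows with out-of-range
#' scores or negative months are rejected with a warning that lists them;
#' a missing `score_overall` is recomputed as the subtest sum divided by 20;
#' an inconsistent one (off by more than 0.05) triggers a warning.
#'
#' @param path CSV path.
#' @return Validated data.frame (class `cohort_table`); rejected rows are
#'   attached as attribute `"rejected"`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) validation_error(paste("file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(df)
}

#' Validate an in-memory cohort table
#'
#' @param df data.frame with the columns listed in [read_cohort_table()].
#' @return Validated data.frame of class `cohort_table`.
#' @export
validate_cohort_table <- function(df) {
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing))
    validation_error(paste("missing cohort columns:",
                           paste(missing, collapse = ", ")))
  if (!all(df$gender %in% c("male", "female", NA)))
    validation_error("gender must be 'male' or 'female'")

  bad <- rep(FALSE, nrow(df))
  why <- character(nrow(df))
  for (col in names(score_ranges)) {
    r <- score_ranges[[col]]
    out <- !is.na(df[[col]]) & (df[[col]] < r[1] | df[[col]] > r[2])
    why[out & !bad] <- paste0(col, " outside [", r[1], ", ", r[2], "]")
    bad <- bad | out
  }
  neg <- !is.na(df$months_post_stroke) & df$months_post_stroke < 0
  why[neg & !bad] <- "negative months_post_stroke"
  bad <- bad | neg
  if (any(bad)) {
    warning(sprintf("rejected %d cohort row(s): %s", sum(bad),
                    paste(sprintf("row %d (%s: %s)", which(bad),
                                  df$patient_id[bad], why[bad]),
                          collapse = "; ")))
  }
  rejected <- df[bad, , drop = FALSE]
  df <- df[!bad, , drop = FALSE]

  subsum <- (df$score_yesno + df$score_word + df$score_commands) / 20
  fill <- is.na(df$score_overall) & !is.na(subsum)
  df$score_overall[fill] <- subsum[fill]
  off <- !is.na(df$score_overall) & !is.na(subsum) &
    abs(df$score_overall - subsum) > 0.05
  if (any(off))
    warning(sprintf(
      "score_overall inconsistent with subtest sum/20 (> 0.05) for row(s): %s",
      paste(which(off), collapse = ", ")))

  rownames(df) <- NULL
  structure(df, rejected = rejected,
            class = c("cohort_table", "data.frame"))
}

#' Write a cohort table as CSV
#'
#' @param df Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a longitudinal comprehension table
#'
#' Expects a CSV with columns `patient_id`, `session_index`,
#' `months_post_onset` and `comprehension_score` (0-10). Months post-onset
#' must be strictly increasing within patient.
#'
#' @param path CSV path.
#' @return Validated data.frame of class `longitudinal_table`, ordered by
#'   patient and session.
#' @export
read_longitudinal_table <- function(path) {
  if (!file.exists(path)) validation_error(paste("file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_longitudinal_table(df)
}

#' Validate an in-memory longitudinal table
#'
#' @param df data.frame with the columns listed in
#'   [read_longitudinal_table()].
#' @return Validated data.frame of class `longitudinal_table`.
#' @export
validate_longitudinal_table <- function(df) {
  missing <- setdiff(longitudinal_columns, names(df))
  if (length(missing))
    validation_error(paste("missing longitudinal columns:",
                           paste(missing, collapse = ", ")))
  if (any(df$comprehension_score < 0 | df$comprehension_score > 10,
          na.rm = TRUE))
    validation_error("comprehension_score must lie in [0, 10]")
  if (any(df$months_post_onset < 0, na.rm = TRUE))
    validation_error("months_post_onset must be non-negative")
  df <- df[order(df$patient_id, df$months_post_onset), , drop = FALSE]
  inc <- tapply(df$months_post_onset, df$patient_id,
                function(m) all(diff(m) > 0))
  if (any(!inc))
    validation_error(paste("months_post_onset not strictly increasing for:",
                           paste(names(inc)[!inc], collapse = ", ")))
  rownames(df) <- NULL
  structure(df, class = c("longitudinal_table", "data.frame"))
}

check_longitudinal <- function(df) {
  missing <- setdiff(c("patient_id", "months_post_onset",
                       "comprehension_score"), names(df))
  if (length(missing))
    validation_error(paste("missing longitudinal columns:",
                           paste(missing, collapse = ", ")))
  invisible(df)
}

#' Apply the recovery-cohort inclusion rules
#'
#' Retains patients who (a) scored below 9 out of 10 on overall auditory
#' comprehension at their first test session (avoiding ceiling effects) and
#' (b) were tested at two or more timepoints with at least two sessions
#' separated by one month or more.
#'
#' @param table A longitudinal data.frame (see [read_longitudinal_table()]).
#' @return The filtered table, same class; all sessions of retained patients
#'   are kept.
#' @export
filter_recovery_cohort <- function(table) {
  check_longitudinal(table)
  df <- table[order(table$patient_id, table$months_post_onset), , drop = FALSE]
  keep_ids <- vapply(split(df, df$patient_id), function(p) {
    nrow(p) >= 2L &&
      p$comprehension_score[1L] < 9 &&
      (max(p$months_post_onset) - min(p$months_post_onset)) >= 1
  }, logical(1L))
  out <- df[df$patient_id %in% names(keep_ids)[keep_ids], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Write a longitudinal table as CSV
#'
#' @param df Longitudinal data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_longitudinal_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}
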