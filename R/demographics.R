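#' Regression of chronic outcome scores on demographic variables
#'
#' Ordinary least squares of an outcome score on months post-stroke, age,
#' gender (male = 1) and education, reported per predictor as the
#' unstandardised coefficient B, its standard error, the standardised
#' coefficient beta (`B * sd(x) / sd(y)`), the two-sided p value and a 95%
#' confidence interval using the exact t quantile at the residual degrees of
#' freedom.
#'
#' @param cohort Cohort data.frame with the four predictors and the outcome.
#' @param outcome Outcome column name (e.g. `"score_word"`).
#' @param predictors Predictor columns (default the four demographic
#'   variables).
#' @return Object of class `regression_report`: a data.frame with one row
#'   per predictor (`term`, `B`, `SE`, `beta`, `t`, `p`, `ci_lo`, `ci_hi`)
#'   and attributes `outcome` and `n`.
#' @export
outcome_regression <- function(cohort, outcome,
                               predictors = c("months_post_stroke", "age",
                                              "gender", "education")) {
  df <- as.data.frame(cohort)
  if (is.null(df[[outcome]]))
    validation_error(paste("missing outcome column:", outcome))
  X <- covariate_matrix(df, predictors)
  y <- as.numeric(df[[outcome]])
  keep <- stats::complete.cases(cbind(y, X))
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(y) < 10L)
    validation_error("need at least 10 complete records")
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    dep <- predictors[qx$pivot[seq.int(qx$rank + 1L, ncol(X) + 1L)] - 1L]
    validation_error(paste("collinear predictors:",
                           paste(dep, collapse = ", ")))
  }
  regression_report(X, y, outcome)
}

## Shared OLS/WLS report builder.
regression_report <- function(X, y, outcome, weights = NULL) {
  dat <- data.frame(y = y, X)
  fml <- stats::as.formula(paste("y ~", paste(colnames(X), collapse = " + ")))
  fit <- if (is.null(weights)) stats::lm(fml, data = dat)
         else stats::lm(fml, data = dat, weights = weights)
  sm <- summary(fit)$coefficients
  df_res <- fit$df.residual
  tq <- stats::qt(0.975, df_res)
  rows <- sm[-1L, , drop = FALSE]   # drop intercept from the report
  out <- data.frame(
    term = rownames(rows),
    B = rows[, 1L],
    SE = rows[, 2L],
    beta = rows[, 1L] * apply(X, 2L, stats::sd)[rownames(rows)] / stats::sd(y),
    t = rows[, 3L],
    p = rows[, 4L],
    ci_lo = rows[, 1L] - tq * rows[, 2L],
    ci_hi = rows[, 1L] + tq * rows[, 2L],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, outcome = outcome, n = length(y), df_residual = df_res,
            class = c("regression_report", "data.frame"))
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Regression of %s (n = %d):\n", attr(x, "outcome"), attr(x, "n")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-20s B = %6.3f, SE = %5.3f, beta = %6.3f, p = %.4g, 95%% CI (%.3f, %.3f)\n",
      x$term[i], x$B[i], x$SE[i], x$beta[i], x$p[i], x$ci_lo[i], x$ci_hi[i]))
  }
  invisible(x)
}

#' Regression of longitudinal recovery slopes on demographic variables
#'
#' With a single estimated slope per patient the mixed-effects specification
#' degenerates to one observation per group, so the model is fitted as
#' (optionally weighted) least squares of the slope on months post-stroke at
#' final test, age, gender and education.
#'
#' @param slopes data.frame from [extract_slopes()] (`patient_id`, `slope`).
#' @param demographics data.frame with `patient_id` and the predictor
#'   columns.
#' @param predictors Predictor columns (default the four demographic
#'   variables).
#' @param weights Optional per-patient weights (e.g. inverse slope
#'   variances), in `slopes` row order.
#' @return A `regression_report` for the slope outcome.
#' @export
slope_regression <- function(slopes, demographics,
                             predictors = c("months_post_stroke", "age",
                                            "gender", "education"),
                             weights = NULL) {
  missing_ids <- setdiff(slopes$patient_id, demographics$patient_id)
  if (length(missing_ids))
    validation_error(paste("patients missing from demographics:",
                           paste(missing_ids, collapse = ", ")))
  demo <- demographics[match(slopes$patient_id, demographics$patient_id), ,
                       drop = FALSE]
  X <- covariate_matrix(demo, predictors)
  regression_report(X, slopes$slope, "recovery_slope", weights = weights)
}
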