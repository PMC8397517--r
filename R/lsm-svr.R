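#' Specification for multivariate (SVR) lesion-symptom mapping
#'
#' Defaults follow the multivariate lesion-symptom mapping literature:
#' epsilon-SVR with an RBF kernel, `C = 30`, `gamma = 5`, `epsilon = 0.1`,
#' and direct total lesion volume control (dTLVC) on. The linear kernel is
#' retained for oracle testing and interpretability.
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C Regularisation constant (> 0).
#' @param gamma RBF kernel width (> 0; ignored for linear).
#' @param epsilon Insensitivity tube half-width (>= 0).
#' @param dtlvc Apply lesion-size normalisation ([dtlvc_normalize()]).
#' @param n_perm Permutations for the maximum-weight null (default 10000).
#' @param alpha Familywise error level (default 0.05).
#' @param seed Seed for the permutation stream.
#' @return Object of class `svr_spec`.
#' @export
svr_spec <- function(kernel = c("rbf", "linear"), C = 30, gamma = 5,
                     epsilon = 0.1, dtlvc = TRUE, n_perm = 10000L,
                     alpha = 0.05, seed = 1L) {
  kernel <- match.arg(kernel)
  if (C <= 0) config_error("C must be positive")
  if (epsilon < 0) config_error("epsilon must be non-negative")
  if (kernel == "rbf" && gamma <= 0) config_error("gamma must be positive")
  if (alpha <= 0 || alpha >= 1) config_error("alpha must lie in (0, 1)")
  structure(list(kernel = kernel, C = C, gamma = gamma, epsilon = epsilon,
                 dtlvc = dtlvc, n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed)),
            class = "svr_spec")
}

#' Direct total lesion volume control (dTLVC)
#'
#' Scales each patient's binary lesion row by the inverse square root of the
#' patient's lesioned-voxel count, so that every row has unit sum of squares
#' and large lesions do not dominate the kernel. Patients with no lesioned
#' voxel inside the analyzable mask cannot be normalised and are excluded
#' with a warning.
#'
#' @param lesion_matrix Binary patients x voxels matrix.
#' @return Real-valued feature matrix; excluded patients (if any) are
#'   dropped and listed in attribute `"excluded"`.
#' @export
dtlvc_normalize <- function(lesion_matrix) {
  counts <- rowSums(lesion_matrix != 0)
  empty <- counts == 0
  if (any(empty)) {
    warning(sprintf("excluding %d patient(s) with no lesioned analyzable voxel: %s",
                    sum(empty),
                    paste(rownames(lesion_matrix)[empty], collapse = ", ")))
  }
  out <- lesion_matrix[!empty, , drop = FALSE] / sqrt(counts[!empty])
  attr(out, "voxels") <- attr(lesion_matrix, "voxels")
  attr(out, "excluded") <- rownames(lesion_matrix)[empty]
  out
}

#' Fit an epsilon-SVR over all voxels jointly and back-project voxel weights
#'
#' All analyzable voxels enter one support vector regression of the
#' behavioral score on the (optionally dTLVC-normalised) lesion features.
#' The per-voxel weight is the back-projection of the dual solution,
#' `w_v = sum_i alpha_i x_iv`, signed so that lesion-associated deficit is
#' positive — for the linear kernel this is exactly the primal weight
#' vector; for the RBF kernel it is the conventional feature-space
#' back-projection used in multivariate lesion-symptom mapping.
#'
#' @param features Patients x voxels feature matrix ([dtlvc_normalize()] or
#'   raw binary).
#' @param scores Numeric outcome vector.
#' @param spec An [svr_spec()].
#' @return List with `weights` (per voxel, deficit-positive), `model` (the
#'   fitted `e1071::svm` object) and `spec`.
#' @export
fit_svr_map <- function(features, scores, spec = svr_spec()) {
  stopifnot(nrow(features) == length(scores))
  if (anyNA(scores) || any(!is.finite(scores)))
    validation_error("scores must be finite")
  model <- tryCatch(
    e1071::svm(x = features, y = scores, type = "eps-regression",
               kernel = if (spec$kernel == "rbf") "radial" else spec$kernel,
               cost = spec$C, gamma = spec$gamma,
               epsilon = spec$epsilon, scale = FALSE, tolerance = 1e-6),
    error = function(e) {
      ## every score inside the epsilon tube: no support vectors, flat map
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
      else stop("SVR solver failed: ", conditionMessage(e))
    })
  if (is.null(model))
    return(list(weights = rep(0, ncol(features)), model = NULL, spec = spec))
  ## back-projection of dual coefficients onto voxels; libsvm's coefs
  ## predict the score, so deficit direction needs the sign flipped
  w <- -drop(crossprod(features[model$index, , drop = FALSE], model$coefs))
  names(w) <- NULL
  list(weights = w, model = model, spec = spec)
}

#' Permutation threshold for the SVR weight map
#'
#' Direct analogue of the univariate maximum-statistic threshold: scores are
#' permuted `n_perm` times, the SVR refitted, and the maximum
#' (deficit-signed) voxel weight recorded; the critical weight is the
#' ceiling-rank `1 - alpha` order statistic of these maxima.
#'
#' @inheritParams fit_svr_map
#' @return List with `critical_w`, `weights` (observed map),
#'   `null_maxima`, and the spec.
#' @export
svr_permutation_threshold <- function(features, scores, spec = svr_spec()) {
  if (spec$n_perm * spec$alpha < 1)
    config_error("n_perm too small for alpha")
  obs <- fit_svr_map(features, scores, spec)
  set.seed(spec$seed)
  n <- length(scores)
  maxima <- vapply(seq_len(spec$n_perm), function(i) {
    fit <- fit_svr_map(features, scores[sample.int(n)], spec)
    max(fit$weights)
  }, numeric(1L))
  k <- ceiling((1 - spec$alpha) * spec$n_perm)
  list(critical_w = sort(maxima)[k], weights = obs$weights,
       null_maxima = maxima, spec = spec)
}

#' Run the multivariate (SVR) lesion-symptom mapping pipeline
#'
#' Builds the analyzable mask exactly as the univariate pipeline does,
#' residualises the score against the design covariates (the multivariate
#' analogue of entering them as nuisance regressors), normalises features
#' with dTLVC when requested, fits the SVR weight map, thresholds it by
#' maximum-weight permutation and reports clusters and peak.
#'
#' @param cohort Validated cohort table.
#' @param lesions List of [lesion_volume()].
#' @param spec An [svr_spec()].
#' @param design A [design_spec()] supplying score, covariates and minimum
#'   overlap.
#' @return A `stat_map` whose statistic is the back-projected SVR weight.
#' @export
run_svr_lsm <- function(cohort, lesions, spec = svr_spec(),
                        design = design_spec()) {
  ids <- vapply(lesions, `[[`, "", "patient_id")
  cohort <- as.data.frame(cohort)
  cohort <- cohort[match(ids, cohort$patient_id), , drop = FALSE]
  cm <- cbind(cohort[[design$score]], covariate_matrix(cohort, design$covariates))
  complete <- stats::complete.cases(cm)
  dropped <- ids[!complete]
  if (length(dropped)) {
    warning(sprintf("dropping %d patient(s) with missing data: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    lesions <- lesions[complete]
    cohort <- cohort[complete, , drop = FALSE]
  }
  overlay <- compute_overlay(lesions)
  mask <- coverage_mask(overlay, design$min_overlap)
  if (!any(mask)) validation_error("no analyzable voxels at this overlap")
  L <- build_lesion_matrix(lesions, mask)
  feats <- if (spec$dtlvc) dtlvc_normalize(L) else L
  kept <- setdiff(rownames(L), attr(feats, "excluded"))
  rows <- match(kept, cohort$patient_id)
  scores <- cohort[[design$score]][rows]
  covs <- covariate_matrix(cohort[rows, , drop = FALSE], design$covariates)
  scores <- qr.resid(qr(cbind(1, covs)), scores)
  perm <- svr_permutation_threshold(feats, scores, spec)
  w_array <- array(NA_real_, dim(mask))
  w_array[attr(L, "voxels")] <- perm$weights
  cl <- threshold_and_cluster(w_array, perm$critical_w, overlay$affine)
  structure(list(
    t_array = w_array,
    critical_t = perm$critical_w,
    mask = mask,
    clusters = cl$clusters,
    peak = cl$peak,
    n_suprathreshold = cl$n_suprathreshold,
    null_maxima = perm$null_maxima,
    n_patients = length(kept),
    dropped = c(dropped, attr(feats, "excluded")),
    spec = spec,
    affine = overlay$affine,
    statistic = "w"
  ), class = "stat_map")
}
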