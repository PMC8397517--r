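#' Run the univariate lesion-symptom mapping pipeline
#'
#' Composes the full univariate analysis: overlay and coverage mask at the
#' configured minimum overlap, voxel-wise covariate-adjusted t statistics
#' ([voxel_regression()]), the maximum-statistic permutation threshold
#' ([max_stat_permutation()]), and cluster/peak reporting
#' ([threshold_and_cluster()]). Patients with a missing score or covariate
#' are dropped with a warning before any voxel is touched.
#'
#' @param cohort Validated cohort table ([read_cohort_table()]).
#' @param lesions List of [lesion_volume()] aligned on one grid; ids must
#'   match `cohort$patient_id`.
#' @param spec A [design_spec()].
#' @return Object of class `stat_map`: `t_array` (3D, `NA` outside the
#'   analyzable mask), `critical_t`, `mask`, `clusters`, `peak`,
#'   `null_maxima`, `n_patients`, `dropped`, `spec`, `affine`.
#' @export
run_univariate_lsm <- function(cohort, lesions, spec = design_spec()) {
  ids <- vapply(lesions, `[[`, "", "patient_id")
  cohort <- as.data.frame(cohort)
  if (!all(ids %in% cohort$patient_id))
    validation_error(paste("lesions without cohort rows:",
                           paste(setdiff(ids, cohort$patient_id), collapse = ", ")))
  cohort <- cohort[match(ids, cohort$patient_id), , drop = FALSE]

  need <- c(spec$score, spec$covariates)
  cm <- cbind(cohort[[spec$score]], covariate_matrix(cohort, spec$covariates))
  complete <- stats::complete.cases(cm)
  dropped <- ids[!complete]
  if (length(dropped)) {
    warning(sprintf("dropping %d patient(s) with missing %s: %s",
                    length(dropped), paste(need, collapse = "/"),
                    paste(dropped, collapse = ", ")))
    lesions <- lesions[complete]
    cohort <- cohort[complete, , drop = FALSE]
  }
  n <- length(lesions)

  overlay <- compute_overlay(lesions)
  mask <- coverage_mask(overlay, spec$min_overlap)
  ## lesion-status contrast also needs at least one intact patient per voxel
  mask[overlay$counts >= n] <- FALSE
  if (!any(mask)) validation_error("no analyzable voxels at this overlap")

  L <- build_lesion_matrix(lesions, mask)
  scores <- cohort[[spec$score]]
  covs <- covariate_matrix(cohort, spec$covariates)
  tvals <- voxel_regression(L, scores, covs)
  perm <- max_stat_permutation(L, scores, covs, n_perm = spec$n_perm,
                               alpha = spec$alpha, seed = spec$seed,
                               scheme = spec$scheme)
  t_array <- array(NA_real_, dim(mask))
  t_array[attr(L, "voxels")] <- tvals
  cl <- threshold_and_cluster(t_array, perm$critical_t, overlay$affine)
  structure(list(
    t_array = t_array,
    critical_t = perm$critical_t,
    mask = mask,
    clusters = cl$clusters,
    peak = cl$peak,
    n_suprathreshold = cl$n_suprathreshold,
    null_maxima = perm$null_maxima,
    n_patients = n,
    dropped = dropped,
    spec = spec,
    affine = overlay$affine,
    statistic = "t"
  ), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("%s lesion-symptom map: %d patients, %d analyzable voxels\n",
              if (x$statistic == "t") "Univariate" else "SVR",
              x$n_patients, sum(x$mask)))
  cat(sprintf("  %s-threshold = %.3f (alpha = %g, %d permutations, %s)\n",
              x$statistic, x$critical_t, x$spec$alpha,
              x$spec$n_perm, x$spec$scheme %||% "score permutation"))
  if (is.null(x$peak)) {
    cat("  no suprathreshold voxels\n")
  } else {
    cat(sprintf("  %s-max = %.2f at %s, largest cluster = %d voxels (%d clusters)\n",
                x$statistic, x$peak$stat, format_mm(x$peak$mm),
                if (nrow(x$clusters)) x$clusters$size[1] else 0L,
                nrow(x$clusters)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a statistic map to disk
#'
#' Writes the statistic volume (float32), the thresholded binary map
#' (uint8) and a JSON sidecar with the threshold, peak, clusters, seed and
#' analysis specification.
#'
#' @param sm A `stat_map`.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default the statistic name).
#' @return Character vector of paths written, invisibly.
#' @export
write_stat_map <- function(sm, dir, prefix = NULL) {
  stopifnot(inherits(sm, "stat_map"))
  if (is.null(prefix)) prefix <- paste0(sm$statistic, "map")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- sm$t_array
  arr[is.na(arr)] <- 0
  p1 <- file.path(dir, paste0(prefix, ".nii.gz"))
  write_nifti_array(arr, sm$affine, p1, datatype = "float")
  thr <- array(as.integer(!is.na(sm$t_array) & sm$t_array > sm$critical_t),
               dim(sm$t_array))
  p2 <- file.path(dir, paste0(prefix, "_thresholded.nii.gz"))
  write_nifti_array(thr, sm$affine, p2, datatype = "uint8")
  p3 <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(
    statistic = sm$statistic,
    critical_value = sm$critical_t,
    alpha = sm$spec$alpha,
    n_perm = sm$spec$n_perm,
    seed = sm$spec$seed,
    n_patients = sm$n_patients,
    n_analyzable_voxels = sum(sm$mask),
    peak = sm$peak,
    clusters = sm$clusters,
    spec = unclass(sm$spec)
  ), p3, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(p1, p2, p3))
}
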