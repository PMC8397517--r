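#' Design specification for univariate lesion-symptom mapping
#'
#' @param score Outcome column of the cohort table (default `score_word`).
#' @param covariates Nuisance covariate columns; the defaults are age,
#'   gender, months post-stroke, overall aphasia severity (WAB AQ) and
#'   lesion volume.
#' @param min_overlap Minimum lesioned patients per analyzable voxel
#'   (default 5).
#' @param n_perm Number of permutations for the maximum-statistic null
#'   (default 10000).
#' @param alpha Familywise error level (default 0.05).
#' @param scheme Permutation scheme: `"freedman_lane"` (default; permute the
#'   residuals of the covariate-only model and re-add its fitted values,
#'   preserving exchangeability under nuisance covariates) or `"raw"`
#'   (permute scores directly).
#' @param seed Seed for the permutation stream.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(score = "score_word",
                        covariates = c("age", "gender", "months_post_stroke",
                                       "wab_aq", "lesion_volume_cc"),
                        min_overlap = 5L, n_perm = 10000L, alpha = 0.05,
                        scheme = c("freedman_lane", "raw"), seed = 1L) {
  if (alpha <= 0 || alpha >= 1) config_error("alpha must lie in (0, 1)")
  if (n_perm < 1L) config_error("n_perm must be >= 1")
  if (min_overlap < 1L) config_error("min_overlap must be >= 1")
  structure(list(score = score, covariates = covariates,
                 min_overlap = as.integer(min_overlap),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 scheme = match.arg(scheme), seed = as.integer(seed)),
            class = "design_spec")
}

#' Patients-by-voxels lesion matrix over a mask
#'
#' @param lesions List of [lesion_volume()] on a common grid.
#' @param mask 3D logical array of voxels to extract (e.g. from
#'   [coverage_mask()]); `NULL` takes every voxel.
#' @return Binary matrix (patients x voxels) with `patient_id` rownames and
#'   attribute `"voxels"` holding the linear grid indices of its columns.
#' @export
build_lesion_matrix <- function(lesions, mask = NULL) {
  stopifnot(length(lesions) >= 1L)
  d <- dim(lesions[[1L]]$grid)
  idx <- if (is.null(mask)) seq_len(prod(d)) else which(mask)
  m <- do.call(rbind, lapply(lesions, function(v) v$grid[idx]))
  rownames(m) <- vapply(lesions, `[[`, "", "patient_id")
  attr(m, "voxels") <- idx
  m
}

## Encode covariates for regression: gender becomes male=1, female=0.
covariate_matrix <- function(cohort, covariates) {
  cols <- lapply(covariates, function(cn) {
    x <- cohort[[cn]]
    if (is.null(x)) validation_error(paste("missing covariate column:", cn))
    if (cn == "gender" || is.character(x) || is.factor(x))
      as.numeric(as.character(x) == "male")
    else as.numeric(x)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Voxel-wise lesion t statistics with covariate adjustment
#'
#' At every voxel a multiple regression `score ~ lesion + covariates` is
#' fitted across patients and the t statistic of the lesion indicator is
#' returned, signed so that lesion-associated deficit (damage predicting a
#' lower score) is positive. Computation residualises the score and every
#' lesion column against the covariates once (Frisch-Waugh), so the whole
#' map is two matrix products rather than one `lm()` per voxel.
#'
#' Voxels whose lesion column has no contrast left after residualisation
#' (constant, or collinear with the covariates) are flagged `NA`. If both
#' the numerator and the residual variance vanish (e.g. all scores equal),
#' the t value is 0.
#'
#' @param lesion_matrix Binary patients x voxels matrix
#'   ([build_lesion_matrix()]).
#' @param scores Numeric outcome vector, one per patient.
#' @param covariates Numeric matrix of nuisance covariates (no intercept
#'   column; one is added), or `NULL` for an intercept-only reduced model.
#' @return Numeric vector of t values per voxel (`NA` = not analyzable),
#'   with attribute `"df"` (residual degrees of freedom).
#' @export
voxel_regression <- function(lesion_matrix, scores, covariates = NULL) {
  n <- nrow(lesion_matrix)
  stopifnot(length(scores) == n)
  if (anyNA(scores) || (!is.null(covariates) && anyNA(covariates)))
    validation_error("missing values in scores or covariates")
  Z <- cbind(intercept = rep(1, n), covariates)
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    validation_error("covariate design is rank deficient")
  ry <- qr.resid(qz, scores)
  RL <- qr.resid(qz, lesion_matrix)
  df <- n - ncol(Z) - 1L
  if (df < 1L) validation_error("not enough patients for the design")
  t_from_residualized(RL, ry, df)
}

## Shared kernel: t of the lesion coefficient from covariate-residualised
## lesion columns RL and score vector ry (deficit-positive sign).
t_from_residualized <- function(RL, ry, df, s = NULL, tol = 1e-10) {
  if (is.null(s)) s <- colSums(RL^2)
  cc <- as.vector(crossprod(RL, ry))
  sy <- sum(ry^2)
  ok <- s > tol
  t <- rep(NA_real_, length(s))
  mse <- pmax(sy - cc[ok]^2 / s[ok], 0) / df
  num <- cc[ok] / sqrt(s[ok])
  tv <- ifelse(mse < tol^2,
               ifelse(abs(num) < tol, 0, sign(num) * Inf),
               num / sqrt(mse))
  t[ok] <- -tv   # deficit (lesion -> lower score) is positive
  attr(t, "df") <- df
  t
}

#' Maximum-statistic permutation threshold for voxel-wise t maps
#'
#' Builds the null distribution of the whole-map maximum t under `n_perm`
#' permutations and returns its upper `1 - alpha` empirical quantile,
#' taken as the ceiling-rank order statistic (conservative). Under the
#' default Freedman-Lane scheme the residuals of the covariate-only model
#' are permuted and the covariate fit re-added before recomputing every
#' voxel's t; with `scheme = "raw"` the scores themselves are permuted.
#'
#' @inheritParams voxel_regression
#' @param n_perm Number of permutations.
#' @param alpha Familywise error level; `n_perm * alpha` must be at least 1.
#' @param seed Seed for the permutation stream.
#' @param scheme `"freedman_lane"` or `"raw"`.
#' @param block Permutations processed per matrix product (memory knob).
#' @return List with `critical_t`, the vector `null_maxima` (length
#'   `n_perm`), `alpha`, `n_perm`, `scheme`, `seed`.
#' @export
max_stat_permutation <- function(lesion_matrix, scores, covariates = NULL,
                                 n_perm = 10000L, alpha = 0.05, seed = 1L,
                                 scheme = c("freedman_lane", "raw"),
                                 block = 500L) {
  scheme <- match.arg(scheme)
  if (n_perm * alpha < 1) config_error("n_perm too small for alpha")
  n <- nrow(lesion_matrix)
  Z <- cbind(intercept = rep(1, n), covariates)
  qz <- qr(Z)
  RL <- qr.resid(qz, lesion_matrix)
  s <- colSums(RL^2)
  keep <- s > 1e-10
  RLk <- RL[, keep, drop = FALSE]
  sk <- s[keep]
  df <- n - ncol(Z) - 1L
  base <- if (scheme == "freedman_lane") qr.resid(qz, scores) else scores
  set.seed(seed)
  maxima <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    P <- vapply(seq_len(nb), function(i) sample.int(n), integer(n))
    V <- matrix(base[P], n, nb)
    YR <- qr.resid(qz, V)
    CC <- crossprod(RLk, YR)                    # voxels x perms
    sy <- colSums(YR^2)
    num <- CC / sqrt(sk)
    mse <- pmax(sweep(-CC^2 / sk, 2L, sy, `+`), 0) / df
    tmat <- -num / sqrt(pmax(mse, 1e-300))      # deficit-positive
    maxima[done + seq_len(nb)] <- apply(tmat, 2L, max)
    done <- done + nb
  }
  k <- ceiling((1 - alpha) * n_perm)
  list(critical_t = sort(maxima)[k], null_maxima = maxima,
       alpha = alpha, n_perm = n_perm, scheme = scheme, seed = seed)
}
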