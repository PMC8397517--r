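## Shared fixtures and independent oracles used across test files.

## Simple axis-aligned affine: voxel edge `vox` mm, origin at voxel (0,0,0).
test_affine <- function(vox = 1) {
  a <- diag(c(vox, vox, vox, 1))
  a
}

make_lesion <- function(arr, vox = 1, id = "T01") {
  lesion_volume(arr, test_affine(vox), id)
}

## Random small LSM instance: binary lesion matrix with guaranteed contrast,
## a score vector and q covariates.
rand_lsm_instance <- function(n = 20, V = 12, q = 3, seed = 1) {
  set.seed(seed)
  repeat {
    L <- matrix(rbinom(n * V, 1, runif(1, 0.3, 0.6)), n, V)
    cs <- colSums(L)
    if (all(cs >= 2 & cs <= n - 2)) break
  }
  Z <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("c", 1:q)))
  y <- rnorm(n, 10, 3)
  list(L = L, Z = Z, y = y)
}

## Independent per-voxel OLS oracle: solves the normal equations of
## score ~ 1 + lesion + covariates voxel by voxel and returns the lesion
## t statistic with the deficit-positive sign convention.
ols_t_oracle <- function(L, y, Z = NULL) {
  n <- length(y)
  vapply(seq_len(ncol(L)), function(v) {
    X <- cbind(1, L[, v], Z)
    XtX <- crossprod(X)
    b <- solve(XtX, crossprod(X, y))
    r <- y - X %*% b
    s2 <- sum(r^2) / (n - ncol(X))
    se <- sqrt(s2 * solve(XtX)[2, 2])
    -(b[2] / se)
  }, numeric(1))
}

## All permutations of 1..n (small n only), as an n! x n matrix.
perms_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

## Small well-formed cohort data.frame for table tests.
toy_cohort <- function(n = 12, seed = 1) {
  set.seed(seed)
  yn <- round(runif(n, 30, 60)); wd <- round(runif(n, 20, 60))
  cm <- round(runif(n, 20, 80))
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    age = round(runif(n, 35, 85)),
    gender = sample(c("male", "female"), n, TRUE),
    education = round(runif(n, 12, 22)),
    months_post_stroke = round(runif(n, 12, 200)),
    wab_aq = round(runif(n, 20, 100), 1),
    lesion_volume_cc = round(runif(n, 5, 300), 1),
    score_yesno = yn, score_word = wd, score_commands = cm,
    score_overall = (yn + wd + cm) / 20,
    stringsAsFactors = FALSE
  )
}
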