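test_that("voxel t statistics match the brute-force OLS oracle", {
  for (s in 1:10) {
    inst <- rand_lsm_instance(n = 20, V = 12, q = 3, seed = s)
    t_pkg <- voxel_regression(inst$L, inst$y, inst$Z)
    t_ora <- ols_t_oracle(inst$L, inst$y, inst$Z)
    expect_equal(as.numeric(t_pkg), t_ora, tolerance = 1e-10)
  }
})

test_that("degenerate voxels are handled: equal scores give t = 0,
           contrast-free voxels are flagged", {
  inst <- rand_lsm_instance(n = 16, V = 6, seed = 3)
  t0 <- voxel_regression(inst$L, rep(7, 16), inst$Z)
  expect_true(all(t0 == 0))

  L <- inst$L
  L[, 2] <- 1L                     # lesioned in everyone: no contrast
  L[, 5] <- 0L
  tv <- voxel_regression(L, inst$y, inst$Z)
  expect_true(is.na(tv[2]))
  expect_true(is.na(tv[5]))
  expect_false(anyNA(tv[c(1, 3, 4, 6)]))
})

test_that("dropping a covariate changes the t map", {
  inst <- rand_lsm_instance(n = 25, V = 10, q = 3, seed = 8)
  t_full <- voxel_regression(inst$L, inst$y, inst$Z)
  t_red <- voxel_regression(inst$L, inst$y, inst$Z[, 1:2])
  expect_false(isTRUE(all.equal(as.numeric(t_full), as.numeric(t_red))))
})

test_that("the permutation threshold is deterministic and validates alpha", {
  inst <- rand_lsm_instance(n = 18, V = 8, seed = 5)
  a <- max_stat_permutation(inst$L, inst$y, inst$Z, n_perm = 200, seed = 42)
  b <- max_stat_permutation(inst$L, inst$y, inst$Z, n_perm = 200, seed = 42)
  expect_identical(a$critical_t, b$critical_t)
  expect_identical(a$null_maxima, b$null_maxima)
  expect_error(max_stat_permutation(inst$L, inst$y, inst$Z,
                                    n_perm = 10, alpha = 0.05),
               class = "lsmrecov_config_error")
})

test_that("alpha = 0.5 returns the median order statistic of the maxima", {
  inst <- rand_lsm_instance(n = 15, V = 6, seed = 6)
  r <- max_stat_permutation(inst$L, inst$y, inst$Z, n_perm = 101,
                            alpha = 0.5, seed = 1)
  expect_equal(r$critical_t, stats::median(r$null_maxima))
})

test_that("Monte-Carlo threshold agrees with exhaustive enumeration on a
           7-patient instance", {
  set.seed(77)
  repeat {
    L <- matrix(rbinom(21, 1, 0.5), 7, 3)
    if (all(colSums(L) >= 2 & colSums(L) <= 5)) break
  }
  y <- rnorm(7, 10, 2)
  ## exhaustive null of the maximum t over all 5040 orderings (oracle OLS)
  P <- perms_of(7)
  ex_max <- apply(P, 1, function(p) max(ols_t_oracle(L, y[p])))
  k <- ceiling(0.95 * length(ex_max))
  ex_sorted <- sort(ex_max)
  mc <- max_stat_permutation(L, y, NULL, n_perm = 3000, alpha = 0.05,
                             seed = 12, scheme = "raw")
  ## MC estimate must land among the neighbouring order statistics
  expect_gte(mc$critical_t, ex_sorted[k - 60])
  expect_lte(mc$critical_t, ex_sorted[min(k + 60, length(ex_sorted))])
})

test_that("clusters partition the suprathreshold voxels with 26-connectivity", {
  arr <- array(NA_real_, c(10, 10, 4))
  arr[, , ] <- 0
  blob1 <- cbind(c(2, 3, 3, 4, 3), c(2, 2, 3, 3, 4), c(2, 2, 2, 2, 2))
  blob2 <- cbind(c(8, 9, 9), c(8, 9, 8), c(3, 4, 3))   # diagonal contacts
  arr[blob1] <- c(5, 6, 7, 5, 5)
  arr[blob2] <- c(4.5, 5.5, 6.5)
  cl <- threshold_and_cluster(arr, 4, test_affine(2))
  expect_setequal(cl$clusters$size, c(5L, 3L))
  expect_equal(cl$n_suprathreshold, sum(cl$clusters$size))
  expect_equal(cl$peak$stat, 7)
  expect_equal(cl$peak$ijk, c(2L, 2L, 1L))      # 0-based
  expect_equal(cl$peak$mm, c(4, 4, 2))          # via the 2 mm affine

  none <- threshold_and_cluster(arr, 100, test_affine())
  expect_equal(nrow(none$clusters), 0L)
  expect_null(none$peak)
})

test_that("raising the overlap requirement only shrinks the analyzable mask
           and the end-to-end map records provenance", {
  cfg <- simulation_config(n_patients = 30L, grid_shape = c(16L, 20L, 16L),
                           mean_volume_cc = 15, seed = 3)
  les <- generate_lesions(cfg)
  coh <- generate_outcomes(les, cfg)
  prev <- NULL
  for (k in c(3L, 5L, 8L)) {
    sm <- run_univariate_lsm(coh, les,
                             design_spec(min_overlap = k, n_perm = 50,
                                         seed = 4))
    if (!is.null(prev)) expect_true(all(sm$mask <= prev))
    prev <- sm$mask
  }
  expect_s3_class(sm, "stat_map")
  expect_equal(sm$spec$seed, 4L)
  expect_equal(sm$n_patients, 30L)
  ## t map inside the mask is the voxel regression on those voxels
  expect_true(all(is.na(sm$t_array[!sm$mask])))
})

test_that("Freedman-Lane and raw-score permutation give different but
           same-scale thresholds", {
  inst <- rand_lsm_instance(n = 30, V = 20, q = 3, seed = 10)
  fl <- max_stat_permutation(inst$L, inst$y, inst$Z, n_perm = 300, seed = 2,
                             scheme = "freedman_lane")
  rw <- max_stat_permutation(inst$L, inst$y, inst$Z, n_perm = 300, seed = 2,
                             scheme = "raw")
  expect_false(identical(fl$null_maxima, rw$null_maxima))
  expect_lt(abs(fl$critical_t - rw$critical_t), 1.5)
})
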