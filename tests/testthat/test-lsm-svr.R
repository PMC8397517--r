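test_that("dTLVC scales rows to unit sum of squares and excludes empty rows", {
  L <- rbind(a = c(1, 1, 1, 1, 0), b = c(1, 0, 0, 0, 0),
             c = c(0, 0, 0, 0, 0), d = c(1, 1, 0, 0, 1))
  expect_warning(f <- dtlvc_normalize(L), "no lesioned")
  expect_equal(attr(f, "excluded"), "c")
  expect_equal(unname(f["a", 1:4]), rep(0.5, 4))   # 1/sqrt(4)
  expect_equal(unname(rowSums(f^2)), rep(1, 3))
})

test_that("a single informative voxel attains the maximum absolute weight", {
  set.seed(13)
  n <- 40; V <- 15
  L <- matrix(rbinom(n * V, 1, 0.5), n, V)
  y <- 20 - 8 * L[, 4]
  f <- dtlvc_normalize(L)
  fit <- fit_svr_map(f, y, svr_spec(kernel = "linear"))
  expect_equal(which.max(abs(fit$weights)), 4L)
  expect_gt(fit$weights[4], 0)   # deficit-positive sign
})

test_that("linear-kernel weights match an independent QP solution of the
           epsilon-SVR dual", {
  skip_if_not_installed("kernlab")
  set.seed(42)
  n <- 5; V <- 3
  X <- matrix(rbinom(n * V, 1, 0.5), n, V)
  X[1, ] <- c(1, 1, 0)
  F <- X / sqrt(pmax(rowSums(X), 1))
  y <- c(10, 8, 5, 7, 3)
  C <- 30; eps <- 0.1
  fit <- fit_svr_map(F, y, svr_spec(kernel = "linear", C = C, epsilon = eps))
  ## dual QP in the split variables (alpha, alpha*), solved by ipop
  K <- F %*% t(F)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(2 * n) * 1e-13
  sol <- kernlab::ipop(c = c(eps - y, eps + y), H = H,
                       A = matrix(c(rep(1, n), rep(-1, n)), 1),
                       b = 0, l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0,
                       sigf = 12, maxiter = 400)
  beta <- kernlab::primal(sol)[1:n] - kernlab::primal(sol)[(n + 1):(2 * n)]
  w_qp <- -drop(t(F) %*% beta)
  expect_equal(fit$weights, w_qp, tolerance = 1e-6)  # 6 significant figures
})

test_that("constant scores produce an all-zero weight map", {
  set.seed(2)
  F <- dtlvc_normalize(matrix(rbinom(60, 1, 0.6), 10, 6))
  fit <- fit_svr_map(F, rep(4, 10), svr_spec(kernel = "linear"))
  expect_true(all(abs(fit$weights) <= 1e-8))
})

test_that("the SVR permutation threshold is deterministic given the seed", {
  set.seed(5)
  F <- dtlvc_normalize(matrix(rbinom(200, 1, 0.5), 20, 10))
  y <- rnorm(20)
  a <- svr_permutation_threshold(F, y, svr_spec(n_perm = 50, seed = 7))
  b <- svr_permutation_threshold(F, y, svr_spec(n_perm = 50, seed = 7))
  expect_identical(a$critical_w, b$critical_w)
  expect_identical(a$null_maxima, b$null_maxima)
  expect_error(svr_permutation_threshold(F, y, svr_spec(n_perm = 5)),
               class = "lsmrecov_config_error")
})

test_that("score scaling rescales weights without changing the
           thresholded voxel set", {
  ## homogeneous instance: epsilon 0 and C scaled with the scores
  set.seed(8)
  F <- dtlvc_normalize(matrix(rbinom(300, 1, 0.5), 20, 15))
  y <- rnorm(20, 10, 3)
  s1 <- svr_spec(kernel = "linear", C = 100, epsilon = 0, n_perm = 100,
                 seed = 3)
  s2 <- svr_spec(kernel = "linear", C = 300, epsilon = 0, n_perm = 100,
                 seed = 3)
  r1 <- svr_permutation_threshold(F, y, s1)
  r2 <- svr_permutation_threshold(F, 3 * y, s2)
  expect_equal(r2$weights, 3 * r1$weights, tolerance = 1e-5)
  expect_equal(r2$critical_w, 3 * r1$critical_w, tolerance = 1e-5)
  expect_identical(which(r1$weights > r1$critical_w),
                   which(r2$weights > r2$critical_w))
})

test_that("SVR weight magnitudes track univariate |t| on uncorrelated
           voxels", {
  rho <- vapply(1:20, function(s) {
    set.seed(300 + s)
    n <- 200; V <- 60
    L <- matrix(rbinom(n * V, 1, 0.4), n, V)
    beta <- numeric(V); beta[sample.int(V, 4)] <- runif(4, 2, 5)
    y <- 30 - drop(L %*% beta) + rnorm(n, 0, 2)
    f <- dtlvc_normalize(L)
    w <- fit_svr_map(f, y, svr_spec())$weights     # rbf defaults
    tv <- voxel_regression(L, y)
    suppressWarnings(stats::cor(abs(w), abs(tv), method = "spearman"))
  }, 0)
  expect_gt(stats::median(rho), 0.5)
})

test_that("null SVR maps reject at a rate compatible with alpha", {
  hits <- vapply(1:100, function(s) {
    set.seed(900 + s)
    F <- dtlvc_normalize(matrix(rbinom(30 * 40, 1, 0.5), 30, 40))
    y <- rnorm(30)
    r <- svr_permutation_threshold(F, y, svr_spec(n_perm = 200,
                                                  seed = 1700 + s))
    any(r$weights > r$critical_w)
  }, logical(1))
  expect_gte(sum(hits), qbinom(0.005, 100, 0.05))
  expect_lte(sum(hits), qbinom(0.995, 100, 0.05))
})

test_that("the end-to-end SVR map localises a strong single-region effect", {
  cfg <- simulation_config(n_patients = 60L, grid_shape = c(16L, 20L, 16L),
                           mean_volume_cc = 15, effect_size = 40,
                           residual_sd = 3, seed = 77)
  les <- generate_lesions(cfg)
  coh <- generate_outcomes(les, cfg)
  sm <- run_svr_lsm(coh, les, svr_spec(n_perm = 100, seed = 5),
                    design_spec(min_overlap = 4))
  expect_s3_class(sm, "stat_map")
  expect_gt(sm$n_suprathreshold, 0)
  ## surviving cluster overlaps the generating critical region
  supra <- which(!is.na(sm$t_array) & sm$t_array > sm$critical_t)
  expect_gt(length(intersect(supra, cfg$critical_roi)), 0)
})
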