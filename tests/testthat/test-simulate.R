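test_that("the generator is byte-deterministic given config and seed", {
  cfg <- simulation_config(n_patients = 5L, grid_shape = c(16L, 20L, 16L),
                           mean_volume_cc = 10, seed = 9,
                           recovery = list(n_patients = 6L))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$lesions, `[[`, "grid"),
                   lapply(b$lesions, `[[`, "grid"))
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(as.data.frame(a$longitudinal),
                   as.data.frame(b$longitudinal))
})

test_that("simulation configs round-trip through JSON", {
  cfg <- simulation_config(n_patients = 7L, grid_shape = c(16L, 20L, 16L),
                           mean_volume_cc = 12, seed = 5,
                           recovery = list(n_patients = 9L, slope_sd = 0.4))
  p <- withr::local_tempfile(fileext = ".json")
  write_simulation_config(cfg, p)
  cfg2 <- read_simulation_config(p)
  expect_equal(cfg2$n_patients, 7L)
  expect_equal(cfg2$recovery$slope_sd, 0.4)
  expect_equal(cfg2$critical_roi, cfg$critical_roi)
  ## identical configs generate identical data
  expect_identical(generate_lesions(cfg2)[[1]]$grid,
                   generate_lesions(cfg)[[1]]$grid)
})

test_that("a single lesion hits its target volume as one connected blob", {
  cfg <- simulation_config(n_patients = 1L, grid_shape = c(24L, 24L, 24L),
                           voxel_size_mm = 1, mean_volume_cc = 1,
                           volume_sdlog = 0, seed = 2)
  v <- generate_lesions(cfg)[[1]]
  expect_equal(sum(v$grid), 1000L)          # 1 cc at 1 mm voxels
  cl <- threshold_and_cluster(array(as.numeric(v$grid), dim(v$grid)), 0.5)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$size, 1000L)
})

test_that("realised lesion volumes match the target distribution in mean", {
  cfg <- simulation_config(n_patients = 100L, seed = 31)
  cc <- vapply(generate_lesions(cfg), lesion_volume_cc, 0)
  expect_lt(abs(mean(cc) - 121.8) / 121.8, 0.10)
})

test_that("an oversized volume target is a config error", {
  expect_error(simulation_config(grid_shape = c(8L, 8L, 8L),
                                 voxel_size_mm = 1, mean_volume_cc = 500) |>
                 generate_lesions(),
               class = "lsmrecov_config_error")
  expect_error(simulation_config(recovery = list(session_count_probs = c(1, 1))),
               class = "lsmrecov_config_error")
})

test_that("with zero effect size lesions carry no score information", {
  cfg <- simulation_config(n_patients = 300L, grid_shape = c(20L, 24L, 20L),
                           mean_volume_cc = 30, effect_size = 0,
                           residual_sd = 0, seed = 17)
  les <- generate_lesions(cfg)
  coh <- generate_outcomes(les, cfg)
  ## independent OLS of score on damage fraction given the covariates:
  ## noise-free scores are an exact function of the covariates alone
  fit <- lm(score_word ~ frac_damage + age + I(gender == "male") +
              education + months_post_stroke + wab_aq, data = coh)
  expect_lt(abs(coef(fit)["frac_damage"]), 1e-8)
})

test_that("a positive effect size yields the expected deficit association", {
  cfg <- simulation_config(n_patients = 500L, grid_shape = c(20L, 24L, 20L),
                           mean_volume_cc = 30, effect_size = 30,
                           residual_sd = 5, seed = 19)
  les <- generate_lesions(cfg)
  coh <- generate_outcomes(les, cfg)
  fit <- lm(score_word ~ frac_damage + age + I(gender == "male") +
              education + months_post_stroke + wab_aq, data = coh)
  sm <- summary(fit)$coefficients["frac_damage", ]
  expect_lt(sm[1], 0)            # damage lowers the score
  expect_lt(sm[4], 0.01)
})

test_that("longitudinal scores follow baseline + slope * f(MPO) exactly
           when noise-free", {
  cfg <- simulation_config(seed = 23,
                           recovery = list(n_patients = 40L, residual_sd = 0))
  lg <- generate_longitudinal(cfg)
  ts <- attr(lg, "true_slopes")
  f <- function(t) 1 / (1 + (t / 8)^(-0.9))   # printed curve, test-side
  ids <- match(lg$patient_id, sprintf("L%03d", seq_along(ts)))
  per <- split(seq_len(nrow(lg)), lg$patient_id)
  for (i in per[1:5]) {
    slope <- ts[ids[i[1]]]
    base <- lg$comprehension_score[i[1]] - slope * f(lg$months_post_onset[i[1]])
    pred <- pmin(pmax(base + slope * f(lg$months_post_onset[i]), 0), 10)
    expect_equal(lg$comprehension_score[i], pred, tolerance = 1e-10)
  }
  ## inclusion rules hold by construction
  expect_identical(nrow(filter_recovery_cohort(lg)), nrow(lg))
  expect_true(all(lg$comprehension_score >= 0 & lg$comprehension_score <= 10))
})

test_that("noise-free per-patient OLS slopes recover the generating mean", {
  cfg <- simulation_config(seed = 21,
                           recovery = list(n_patients = 1000L, residual_sd = 0))
  lg <- generate_longitudinal(cfg)
  f <- function(t) 1 / (1 + (t / 8)^(-0.9))
  x <- f(lg$months_post_onset)
  ols <- vapply(split(seq_len(nrow(lg)), lg$patient_id), function(i) {
    if (stats::sd(x[i]) > 0)
      stats::cov(x[i], lg$comprehension_score[i]) / stats::var(x[i])
    else NA_real_
  }, 0)
  expect_lt(abs(mean(ols, na.rm = TRUE) - 3.71), 0.1)
  ## session counts average about 2.7
  expect_lt(abs(nrow(lg) / 1000 - 2.7), 0.15)
})
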