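#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by the generator: a desk-scale
#' template grid, middle-cerebral-artery-like lesion blobs grown to a target
#' volume distribution (mean 121.8 cc), comprehension scores driven by
#' fractional damage to a designated critical region plus covariate effects
#' and noise, and a longitudinal block in which scores follow
#' `baseline_i + slope_i * f(MPO)` with a log-logistic `f` (scale 8, shape
#' 0.9), slope mean 3.71 and between-patient slope SD 0.60.
#'
#' Covariate marginals follow the cohort the generator emulates: age about
#' 61 (SD 11), education 12-22 years, 79% male. The within-patient residual
#' SD of the longitudinal scores defaults to 1.0 on the 0-10 scale.
#'
#' @param n_patients Cross-sectional cohort size (default 168).
#' @param grid_shape 3D grid dimensions (default `c(32, 40, 32)`).
#' @param voxel_size_mm Isotropic voxel edge in mm (default 4).
#' @param mean_volume_cc Mean lesion volume in cc (default 121.8).
#' @param volume_sdlog Log-normal dispersion of lesion volumes (default 0.4).
#' @param critical_roi Integer vector of linear voxel indices of the critical
#'   region; `NULL` selects a small sphere in the simulated posterior
#'   temporal territory.
#' @param effect_size Score points lost per unit fractional damage to the
#'   critical region (default 30).
#' @param cov_effects Named list of covariate coefficients applied to
#'   centred covariates (age, gender with male = 1, education,
#'   months_post_stroke, wab_aq).
#' @param residual_sd Residual SD of the subtest scores (default 5).
#' @param recovery Named list overriding the longitudinal block defaults:
#'   `n_patients` (44), `family` ("log_logistic"), `scale` (8), `shape`
#'   (0.9), `slope_mean` (3.71), `slope_sd` (0.60), `baseline_mean` (3.5),
#'   `baseline_sd` (1.8), `residual_sd` (1.0), `session_count_probs`
#'   (probabilities for 2..6 sessions, mean about 2.7),
#'   `session_time_range` (log-uniform, months, `c(1, 220)`).
#' @param seed Root seed; all stages derive named sub-seeds from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 168L,
                              grid_shape = c(32L, 40L, 32L),
                              voxel_size_mm = 4,
                              mean_volume_cc = 121.8,
                              volume_sdlog = 0.4,
                              critical_roi = NULL,
                              effect_size = 30,
                              cov_effects = list(age = -0.08, gender = 0.5,
                                                 education = 0.6,
                                                 months_post_stroke = 0.004,
                                                 wab_aq = 0.05),
                              residual_sd = 5,
                              recovery = list(),
                              seed = 1L) {
  if (residual_sd < 0 || volume_sdlog < 0)
    config_error("standard deviations must be non-negative")
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    config_error("grid_shape must be 3 dimensions of at least 8 voxels")
  rec <- utils::modifyList(list(
    n_patients = 44L, family = "log_logistic", scale = 8, shape = 0.9,
    slope_mean = 3.71, slope_sd = 0.60, baseline_mean = 3.5,
    baseline_sd = 1.8, residual_sd = 1.0,
    session_count_probs = c(0.55, 0.25, 0.12, 0.05, 0.03),
    session_time_range = c(1, 220)
  ), recovery)
  if (rec$slope_sd < 0 || rec$residual_sd < 0 || rec$baseline_sd < 0)
    config_error("recovery standard deviations must be non-negative")
  p <- rec$session_count_probs
  if (length(p) != 5L || any(p < 0) || sum(p) <= 0)
    config_error("session_count_probs must be 5 non-negative weights for 2..6 sessions")
  rec$session_count_probs <- p / sum(p)

  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    affine = grid_affine(grid_shape, voxel_size_mm),
    mean_volume_cc = mean_volume_cc,
    volume_sdlog = volume_sdlog,
    effect_size = effect_size,
    cov_effects = cov_effects,
    residual_sd = residual_sd,
    recovery = rec,
    seed = as.integer(seed)
  ), class = "simulation_config")
  cfg$critical_roi <- if (is.null(critical_roi)) default_roi(cfg)
                      else as.integer(critical_roi)
  if (any(cfg$critical_roi < 1L) || any(cfg$critical_roi > prod(grid_shape)))
    config_error("critical_roi indices fall outside the grid")
  cfg
}

## Template affine: isotropic voxels, grid centre at mm origin, RAS-style
## axes; low i maps to negative x, i.e. the modelled (left) hemisphere.
grid_affine <- function(grid_shape, voxel_size_mm) {
  v <- voxel_size_mm
  ctr <- (grid_shape - 1) / 2
  rbind(
    c(v, 0, 0, -v * ctr[1]),
    c(0, v, 0, -v * ctr[2]),
    c(0, 0, v, -v * ctr[3]),
    c(0, 0, 0, 1)
  )
}

## Interior voxels of the modelled (left) hemisphere: i below the midline,
## one-voxel border excluded so neighbourhood arithmetic never wraps.
hemisphere_indices <- function(cfg) {
  d <- cfg$grid_shape
  i <- slice.index(array(0L, d), 1L)
  j <- slice.index(array(0L, d), 2L)
  k <- slice.index(array(0L, d), 3L)
  which(i > 1L & i <= floor(d[1] / 2) & j > 1L & j < d[2] & k > 1L & k < d[3])
}

## Ellipsoidal vascular-territory weight mask (MCA-like): centred laterally
## in the hemisphere, elongated anterior-posterior.
territory_mask <- function(cfg) {
  d <- cfg$grid_shape
  i <- slice.index(array(0L, d), 1L)
  j <- slice.index(array(0L, d), 2L)
  k <- slice.index(array(0L, d), 3L)
  c0 <- c(0.25, 0.52, 0.50) * d
  ax <- c(0.20, 0.40, 0.34) * d
  ((i - c0[1]) / ax[1])^2 + ((j - c0[2]) / ax[2])^2 +
    ((k - c0[3]) / ax[3])^2 <= 1
}

## Default critical region: a small sphere in the posterior part of the
## simulated territory (standing in for posterior middle temporal cortex).
default_roi <- function(cfg) {
  d <- cfg$grid_shape
  i <- slice.index(array(0L, d), 1L)
  j <- slice.index(array(0L, d), 2L)
  k <- slice.index(array(0L, d), 3L)
  c0 <- round(c(0.22, 0.68, 0.42) * d)
  r <- max(2, round(0.06 * min(d)))
  which((i - c0[1])^2 + (j - c0[2])^2 + (k - c0[3])^2 <= r^2)
}

#' Generate synthetic lesion masks
#'
#' Each lesion is grown by randomised 26-connected region growing from a
#' seed voxel inside an elliptical vascular-territory mask in the left
#' hemisphere, with growth biased to stay inside the territory. Target
#' volumes are drawn log-normally with the configured mean; growth stops
#' exactly at the target voxel count, so realised volumes match the draw.
#'
#' @param cfg A [simulation_config()].
#' @return List of `n_patients` [lesion_volume()] objects (ids `P001`, ...).
#' @export
generate_lesions <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  d <- cfg$grid_shape
  nvox <- prod(d)
  hemi <- hemisphere_indices(cfg)
  in_hemi <- logical(nvox); in_hemi[hemi] <- TRUE
  terr <- territory_mask(cfg)
  seeds_from <- hemi[terr[hemi]]
  vox_cc <- prod(rep(cfg$voxel_size_mm, 3L)) / 1000
  mean_target <- cfg$mean_volume_cc / vox_cc
  if (mean_target > length(hemi))
    config_error("target lesion volume exceeds the hemisphere mask")

  set.seed(stage_seed(cfg$seed, "lesions"))
  meanlog <- log(mean_target) - cfg$volume_sdlog^2 / 2
  targets <- pmin(pmax(round(stats::rlnorm(cfg$n_patients, meanlog,
                                           cfg$volume_sdlog)), 1),
                  floor(0.9 * length(hemi)))
  ## 26-neighbourhood linear-index offsets (safe: growth is border-free)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, ]
  loffs <- offs[, 1L] + offs[, 2L] * d[1] + offs[, 3L] * d[1] * d[2]

  lapply(seq_len(cfg$n_patients), function(p) {
    target <- targets[p]
    accepted <- logical(nvox)
    seen <- logical(nvox)
    seed_vox <- sample(seeds_from, 1L)
    accepted[seed_vox] <- TRUE; seen[seed_vox] <- TRUE
    frontier <- unique(seed_vox + loffs)
    frontier <- frontier[in_hemi[frontier]]
    seen[frontier] <- TRUE
    count <- 1L
    while (count < target && length(frontier) > 0L) {
      k <- min(target - count, max(1L, as.integer(0.2 * length(frontier))))
      w <- ifelse(terr[frontier], 1, 0.15)
      pick <- if (length(frontier) == 1L) 1L
              else sample.int(length(frontier), k, prob = w)
      chosen <- frontier[pick]
      accepted[chosen] <- TRUE
      count <- count + length(chosen)
      frontier <- frontier[-pick]
      cand <- unique(as.vector(outer(chosen, loffs, `+`)))
      cand <- cand[cand >= 1L & cand <= nvox]
      cand <- cand[in_hemi[cand] & !seen[cand]]
      seen[cand] <- TRUE
      frontier <- c(frontier, cand)
    }
    lesion_volume(array(as.integer(accepted), d), cfg$affine,
                  sprintf("P%03d", p))
  })
}

## Fraction of the critical region covered by a lesion.
frac_damage <- function(lesion, roi) sum(lesion$grid[roi]) / length(roi)

## Covariate centring constants (the emulated cohort's marginal means).
cov_centres <- c(age = 61.2, gender = 0.79, education = 14.9,
                 months_post_stroke = 51.4, wab_aq = 70.6)

#' Generate cross-sectional outcomes for a set of lesions
#'
#' Draws demographic covariates from the emulated cohort's marginals, then
#' builds each subtest score as a base level minus `effect_size` times the
#' fractional damage to the critical region, plus centred covariate effects
#' and Gaussian noise, clipped to the score range (ceiling/floor effects by
#' clipping). The overall comprehension score is the subtest sum divided
#' by 20.
#'
#' @param lesions List of [lesion_volume()] from [generate_lesions()].
#' @param cfg The same [simulation_config()].
#' @return A validated `cohort_table` with one row per lesion.
#' @export
generate_outcomes <- function(lesions, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- length(lesions)
  set.seed(stage_seed(cfg$seed, "outcomes"))
  age <- clip(stats::rnorm(n, 61.2, 11.2), 31, 86)
  male <- stats::rbinom(n, 1L, 0.79)
  education <- clip(round(stats::rnorm(n, 14.9, 2.4)), 12, 22)
  mpo <- clip(exp(stats::rnorm(n, log(36), 0.8)), 12, 330)
  aq <- clip(stats::rnorm(n, 70.6, 28.3), 9, 100)
  fd <- vapply(lesions, frac_damage, 0, roi = cfg$critical_roi)
  vol <- vapply(lesions, lesion_volume_cc, 0)

  ce <- cfg$cov_effects
  lin <- ce$age * (age - cov_centres["age"]) +
    ce$gender * (male - cov_centres["gender"]) +
    ce$education * (education - cov_centres["education"]) +
    ce$months_post_stroke * (mpo - cov_centres["months_post_stroke"]) +
    ce$wab_aq * (aq - cov_centres["wab_aq"])
  subtest <- function(base, range_hi) {
    clip(base + lin - cfg$effect_size * fd +
           stats::rnorm(n, 0, cfg$residual_sd), 0, range_hi)
  }
  yesno <- subtest(56, 60)
  word <- subtest(54, 60)
  commands <- subtest(70, 80)
  df <- data.frame(
    patient_id = vapply(lesions, `[[`, "", "patient_id"),
    age = age,
    gender = ifelse(male == 1L, "male", "female"),
    education = education,
    months_post_stroke = mpo,
    wab_aq = aq,
    lesion_volume_cc = vol,
    score_yesno = yesno,
    score_word = word,
    score_commands = commands,
    score_overall = (yesno + word + commands) / 20,
    stringsAsFactors = FALSE
  )
  df$frac_damage <- fd
  validate_cohort_table(df)
}

#' Generate a longitudinal recovery table
#'
#' Per patient: a session count drawn from 2..6 (mean about 2.7), session
#' times log-uniform over the configured range (successive sessions forced
#' at least one month apart), a patient slope drawn around the configured
#' mean, and scores `baseline_i + slope_i * f(MPO)` plus noise, clipped to
#' `[0, 10]`. Baselines are resampled until the first-session score is below
#' 9, so every generated patient passes [filter_recovery_cohort()].
#'
#' @param cfg A [simulation_config()]; the `recovery` block supplies the
#'   parameters.
#' @return A validated `longitudinal_table` (ids `L001`, ...); per-patient
#'   demographics for the recovery analyses are attached as attribute
#'   `"demographics"`, and the generating slopes as attribute
#'   `"true_slopes"`.
#' @export
generate_longitudinal <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  rec <- cfg$recovery
  set.seed(stage_seed(cfg$seed, "longitudinal"))
  n <- rec$n_patients
  rows <- vector("list", n)
  true_slopes <- numeric(n)
  f <- function(m) compress_time(rec$family, m, scale = rec$scale,
                                 shape = rec$shape)
  lo <- log(rec$session_time_range[1]); hi <- log(rec$session_time_range[2])
  for (i in seq_len(n)) {
    ns <- sample(2:6, 1L, prob = rec$session_count_probs)
    mpo <- sort(exp(stats::runif(ns, lo, hi)))
    if (ns > 1L) for (j in 2:ns) mpo[j] <- max(mpo[j], mpo[j - 1L] + 1)
    slope <- stats::rnorm(1L, rec$slope_mean, rec$slope_sd)
    fx <- f(mpo)
    for (try in 1:200) {
      baseline <- stats::rnorm(1L, rec$baseline_mean, rec$baseline_sd)
      eps <- stats::rnorm(ns, 0, rec$residual_sd)
      score <- clip(baseline + slope * fx + eps, 0, 10)
      if (score[1L] < 9) break
    }
    true_slopes[i] <- slope
    rows[[i]] <- data.frame(
      patient_id = sprintf("L%03d", i),
      session_index = seq_len(ns),
      months_post_onset = mpo,
      comprehension_score = score,
      stringsAsFactors = FALSE
    )
  }
  out <- validate_longitudinal_table(do.call(rbind, rows))
  demo <- data.frame(
    patient_id = sprintf("L%03d", seq_len(n)),
    age = clip(stats::rnorm(n, 62.2, 10.2), 41, 80),
    gender = ifelse(stats::rbinom(n, 1L, 0.80) == 1L, "male", "female"),
    education = clip(round(stats::rnorm(n, 13.9, 2.2)), 9, 20),
    months_post_stroke = as.numeric(tapply(out$months_post_onset,
                                           out$patient_id, max)),
    stringsAsFactors = FALSE
  )
  attr(out, "demographics") <- demo
  attr(out, "true_slopes") <- true_slopes
  out
}

#' Generate a full synthetic study
#'
#' @param cfg A [simulation_config()].
#' @return List with `lesions`, `cohort` and `longitudinal`.
#' @export
generate_cohort <- function(cfg) {
  lesions <- generate_lesions(cfg)
  list(lesions = lesions,
       cohort = generate_outcomes(lesions, cfg),
       longitudinal = generate_longitudinal(cfg))
}

#' Serialize a simulation configuration as JSON
#'
#' @param cfg A [simulation_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a simulation configuration from JSON
#'
#' @param path JSON path written by [write_simulation_config()].
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  simulation_config(
    n_patients = x$n_patients, grid_shape = x$grid_shape,
    voxel_size_mm = x$voxel_size_mm, mean_volume_cc = x$mean_volume_cc,
    volume_sdlog = x$volume_sdlog, critical_roi = x$critical_roi,
    effect_size = x$effect_size, cov_effects = as.list(x$cov_effects),
    residual_sd = x$residual_sd,
    recovery = as.list(x$recovery), seed = x$seed
  )
}
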