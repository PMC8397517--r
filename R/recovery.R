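#' Fit one time-compression family to a longitudinal table
#'
#' For a candidate family `f(.; scale, shape)`, the comprehension score is
#' modelled as a linear mixed model in compressed time,
#' `score ~ 1 + f(MPO)` with a random intercept and an independent random
#' slope per patient ([lmm_fit()]). The transformation parameters are
#' profiled: every point of a log-spaced grid is fitted, then the best grid
#' point is refined by Nelder-Mead on the log-parameter scale (relative
#' tolerance 1e-6). Model comparison uses maximum likelihood (not REML),
#' because the fixed-effects design changes with the transformation
#' parameters and across families, and REML likelihoods are not comparable
#' across fixed-effects designs.
#'
#' BIC is `-2 logLik + k log(N)` with `N` the number of observations and `k`
#' counting the two fixed effects, the variance parameters (two random-effect
#' SDs and the residual SD, or two when `random_slope = FALSE`), and any
#' transformation parameters that were fitted (zero when `params` is given).
#'
#' @param table Longitudinal data.frame with columns `patient_id`,
#'   `months_post_onset`, `comprehension_score` (see
#'   [read_longitudinal_table()]); it should already satisfy the recovery
#'   inclusion rules ([filter_recovery_cohort()]).
#' @param family Family name from [compression_families()].
#' @param params Optional named numeric vector `c(scale=, shape=)` fixing the
#'   transformation a priori instead of profiling it.
#' @param grid_size Grid points per parameter for the profiling stage
#'   (default 16).
#' @param refine Run Nelder-Mead refinement from the best grid point
#'   (default `TRUE`).
#' @param random_slope Passed to [lmm_fit()].
#' @return An object of class `recovery_fit`: family name, fitted `scale` and
#'   `shape`, `n_params_fitted`, fixed `intercept` and `slope` (score units
#'   per unit compressed time), random-effect SDs, residual SD, `logLik`,
#'   `bic`, `n_obs`, `n_patients`, and the underlying `lmm` fit.
#' @export
fit_family <- function(table, family, params = NULL, grid_size = 16L,
                       refine = TRUE, random_slope = TRUE) {
  family <- match.arg(family, compression_families())
  check_longitudinal(table)
  if (length(unique(table$patient_id)) < 3L)
    stop("need at least 3 patients to fit a recovery model")
  y <- table$comprehension_score
  t <- table$months_post_onset
  g <- factor(table$patient_id)
  st_for <- function(par) {
    x <- compress_time(family, t, scale = par[1],
                       shape = if (length(par) > 1L) par[2] else NULL)
    lmm_suffstats(y, x, g)
  }
  two <- family_n_params(family) == 2L

  if (!is.null(params)) {
    par <- unname(c(params["scale"], if (two) params["shape"]))
    if (anyNA(par)) stop("params must name scale", if (two) " and shape")
    n_fitted <- 0L
  } else {
    rng <- family_grid_range(family)
    sc <- exp(seq(log(rng$scale[1]), log(rng$scale[2]), length.out = grid_size))
    grid <- if (two) {
      sh <- exp(seq(log(rng$shape[1]), log(rng$shape[2]), length.out = grid_size))
      as.matrix(expand.grid(scale = sc, shape = sh))
    } else matrix(sc, ncol = 1L, dimnames = list(NULL, "scale"))
    dev_at <- function(par) {
      st <- st_for(par)
      opt <- tryCatch(
        lmm_optimize(st, reml = FALSE, random_slope = random_slope,
                     starts = list(c(1, 1))),
        error = function(e) list(deviance = Inf))
      opt$deviance
    }
    devs <- apply(grid, 1L, dev_at)
    if (!any(is.finite(devs))) stop("no grid point produced a finite fit")
    par <- grid[which.min(devs), ]
    if (refine) {
      ## Nelder-Mead on the log scale, boxed to the grid range extended 4x
      ## so tiny noisy datasets cannot chase degenerate step-function fits.
      lo <- log(vapply(rng, `[[`, 0, 1L) / 4)
      hi <- log(vapply(rng, `[[`, 0, 2L) * 4)
      if (length(par) == 1L) {
        o <- stats::optimize(function(lp) dev_at(exp(lp)), c(lo, hi),
                             tol = 1e-6)
        if (o$objective <= min(devs)) par <- exp(o$minimum)
      } else {
        o <- stats::optim(log(par), function(lp) {
          if (any(lp < lo) || any(lp > hi)) return(1e10)
          dev_at(exp(lp))
        }, method = "Nelder-Mead",
           control = list(reltol = 1e-6, maxit = 400L))
        if (o$value <= min(devs)) par <- exp(o$par)
      }
    }
    par <- unname(par)
    n_fitted <- length(par)
  }

  st <- st_for(par)
  opt <- lmm_optimize(st, reml = FALSE, random_slope = random_slope,
                      starts = list(c(1, 1), c(0.1, 0.1), c(3, 0.3)))
  x <- compress_time(family, t, scale = par[1],
                     shape = if (two) par[2] else NULL)
  lmm <- lmm_finish(lmm_suffstats(y, x, g), opt$theta, reml = FALSE,
                    group_levels = levels(g))
  k <- 2L + (if (random_slope) 3L else 2L) + n_fitted
  bic <- -2 * lmm$logLik + k * log(lmm$n_obs)
  structure(list(
    family = family,
    scale = par[1],
    shape = if (two) par[2] else NA_real_,
    n_params_fitted = n_fitted,
    intercept = unname(lmm$beta[1]),
    slope = unname(lmm$beta[2]),
    sd_intercept = lmm$sd_intercept,
    sd_slope = lmm$sd_slope,
    sigma = lmm$sigma,
    logLik = lmm$logLik,
    k = k,
    bic = bic,
    n_obs = lmm$n_obs,
    n_patients = lmm$n_groups,
    lmm = lmm
  ), class = "recovery_fit")
}

#' Fit all candidate families and rank them by BIC
#'
#' @inheritParams fit_family
#' @param families Character vector of family names (default: all ten).
#' @return An object of class `recovery_selection`: a list of `recovery_fit`
#'   objects in ascending BIC order (ties broken by family name), with the
#'   best fit first. `summary()`/`print()` render a BIC table.
#' @export
select_best_family <- function(table, families = compression_families(),
                               params = NULL, grid_size = 16L,
                               refine = TRUE, random_slope = TRUE) {
  if (length(families) < 1L) stop("need at least one family")
  fits <- lapply(families, function(fam)
    fit_family(table, fam, params = params, grid_size = grid_size,
               refine = refine, random_slope = random_slope))
  ord <- order(vapply(fits, `[[`, 0, "bic"),
               vapply(fits, `[[`, "", "family"))
  structure(fits[ord], class = "recovery_selection")
}

#' BIC table for a family selection
#'
#' @param object A `recovery_selection` from [select_best_family()].
#' @param ... Unused.
#' @return data.frame with one row per family: family, scale, shape, slope,
#'   logLik, k, bic, in ascending BIC order.
#' @export
summary.recovery_selection <- function(object, ...) {
  data.frame(
    family = vapply(object, `[[`, "", "family"),
    scale = vapply(object, `[[`, 0, "scale"),
    shape = vapply(object, `[[`, 0, "shape"),
    slope = vapply(object, `[[`, 0, "slope"),
    logLik = vapply(object, `[[`, 0, "logLik"),
    k = vapply(object, `[[`, 0L, "k"),
    bic = vapply(object, `[[`, 0, "bic"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.recovery_selection <- function(x, ...) {
  cat("Time-compression family selection (ascending BIC):\n")
  print(summary(x), digits = 5)
  invisible(x)
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("Recovery fit: %s(scale = %.4g%s)\n", x$family, x$scale,
              if (is.na(x$shape)) "" else sprintf(", shape = %.4g", x$shape)))
  cat(sprintf("  slope %.3f (random-slope SD %.3f), intercept %.3f\n",
              x$slope, x$sd_slope, x$intercept))
  cat(sprintf("  logLik %.2f, BIC %.1f (k = %d, N = %d obs, %d patients)\n",
              x$logLik, x$bic, x$k, x$n_obs, x$n_patients))
  invisible(x)
}

#' Per-patient recovery slopes from a fitted model
#'
#' The patient-level slope is the fixed slope plus the BLUP of the patient's
#' random slope deviation; it measures score points gained per unit of
#' compressed time, i.e. over the whole course of recovery.
#'
#' @param fit A `recovery_fit` from [fit_family()].
#' @return data.frame with columns `patient_id`, `slope`, `slope_dev`
#'   (the random deviation) and `intercept_dev`.
#' @export
extract_slopes <- function(fit) {
  stopifnot(inherits(fit, "recovery_fit"))
  re <- fit$lmm$ranef
  data.frame(
    patient_id = re$group,
    slope = fit$slope + re$slope_dev,
    slope_dev = re$slope_dev,
    intercept_dev = re$intercept_dev,
    stringsAsFactors = FALSE
  )
}

#' Fraction of asymptotic improvement reached by given months
#'
#' Evaluates the fitted compression at the requested months post-onset and,
#' optionally, the improvement accrued over intervals — e.g. how much of the
#' total recovery falls between 18 and 24 months versus between 60 and 120
#' months.
#'
#' @param fit A `recovery_fit`.
#' @param months Non-negative months post-onset to evaluate.
#' @param intervals Optional list of length-2 numeric vectors `(a, b)`;
#'   each yields `f(b) - f(a)`.
#' @return data.frame `months`, `fraction`; if `intervals` given, an
#'   attribute `"intervals"` holds a data.frame `from`, `to`, `fraction`.
#' @export
recovery_milestones <- function(fit, months, intervals = NULL) {
  stopifnot(inherits(fit, "recovery_fit"))
  if (any(months < 0)) stop("months must be non-negative")
  f <- function(m) compress_time(fit$family, m, scale = fit$scale,
                                 shape = if (is.na(fit$shape)) NULL else fit$shape)
  out <- data.frame(months = months, fraction = f(months))
  if (!is.null(intervals)) {
    iv <- do.call(rbind, lapply(intervals, function(ab) {
      if (any(ab < 0)) stop("months must be non-negative")
      data.frame(from = ab[1], to = ab[2], fraction = f(ab[2]) - f(ab[1]))
    }))
    attr(out, "intervals") <- iv
  }
  out
}
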