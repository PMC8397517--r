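#' Linear mixed-effects fit with random intercept and (optionally) slope
#'
#' Fits the two-level model
#' \deqn{y_{ik} = \beta_0 + \beta_1 x_{ik} + u_{0i} + u_{1i} x_{ik} +
#'   \varepsilon_{ik}}
#' with independent random effects \eqn{u_{0i} \sim N(0, \sigma_0^2)},
#' \eqn{u_{1i} \sim N(0, \sigma_1^2)} and residual
#' \eqn{\varepsilon_{ik} \sim N(0, \sigma^2)}, by direct optimisation of the
#' profiled deviance. The fixed effects and the residual variance are profiled
#' out analytically, leaving a bounded optimisation over the relative
#' standard deviations \eqn{\theta = (\sigma_0/\sigma, \sigma_1/\sigma)}.
#' Because the random-effects design per patient is only two columns wide,
#' each objective evaluation reduces to 2x2 Woodbury algebra on per-group
#' sufficient statistics, vectorised across groups — a single evaluation is
#' O(number of groups), which is what makes grid-profiling over
#' transformation parameters in [fit_family()] cheap.
#'
#' @param y Numeric response vector.
#' @param x Numeric covariate vector (compressed time in the recovery
#'   analyses).
#' @param group Grouping factor (patient id), same length as `y`.
#' @param reml If `TRUE` (default) optimise the REML criterion; if `FALSE`,
#'   maximum likelihood. ML is required when fits with different fixed-effects
#'   designs are compared (see [fit_family()]).
#' @param random_slope Include the per-group random slope (default `TRUE`).
#' @param starts List of start values for \eqn{\theta} (relative SD scale).
#' @return An object of class `lmm_fit`: a list with elements `beta`
#'   (intercept, slope), `sd_intercept`, `sd_slope`, `sigma`, `theta`,
#'   `logLik`, `deviance`, `reml`, `n_obs`, `n_groups`, `singular` (TRUE when
#'   a variance component collapsed to the boundary), and `ranef`, a
#'   data.frame of best linear unbiased predictions (BLUPs) of the per-group
#'   random intercept and slope deviations.
#' @examples
#' set.seed(1)
#' g <- rep(1:20, each = 3); x <- runif(60)
#' y <- 2 + 3 * x + rnorm(20, 0, 1)[g] + rnorm(60, 0, 0.5)
#' fit <- lmm_fit(y, x, g)
#' fit$beta
#' @export
lmm_fit <- function(y, x, group, reml = TRUE, random_slope = TRUE,
                    starts = list(c(1, 1), c(0.1, 0.1), c(3, 0.3))) {
  stopifnot(length(y) == length(x), length(y) == length(group))
  if (anyNA(y) || anyNA(x)) stop("y and x must not contain missing values")
  group <- as.factor(group)
  tab <- table(group)
  if (sum(tab >= 2L) < 2L)
    stop("need at least 2 groups with at least 2 observations each")
  st <- lmm_suffstats(y, x, group)
  opt <- lmm_optimize(st, reml = reml, random_slope = random_slope,
                      starts = starts)
  lmm_finish(st, opt$theta, reml = reml, group_levels = levels(group))
}

## Per-group sufficient statistics for design Z_i = [1, x]; fixed design
## equals the random design here.
lmm_suffstats <- function(y, x, group) {
  s11 <- as.numeric(rowsum(rep(1, length(y)), group))
  s12 <- as.numeric(rowsum(x, group))
  s22 <- as.numeric(rowsum(x * x, group))
  u1 <- as.numeric(rowsum(y, group))
  u2 <- as.numeric(rowsum(x * y, group))
  yy <- as.numeric(rowsum(y * y, group))
  list(s11 = s11, s12 = s12, s22 = s22, u1 = u1, u2 = u2, yy = yy,
       N = length(y), G = nlevels(group))
}

## Profiled -2 log-likelihood (ML or REML) at relative SDs theta = (t0, t1).
## Returns the deviance with GLS beta, profiled sigma^2 and the per-group
## Woodbury pieces attached for reuse by the BLUP computation.
lmm_profiled_deviance <- function(theta, st, reml = FALSE, keep = FALSE) {
  t0 <- theta[1]; t1 <- if (length(theta) > 1L) theta[2] else 0
  ## W_i = I2 + D^{1/2} S_i D^{1/2}, D = diag(t0^2, t1^2)
  w11 <- 1 + t0^2 * st$s11
  w12 <- t0 * t1 * st$s12
  w22 <- 1 + t1^2 * st$s22
  detW <- w11 * w22 - w12^2
  ## Q_i = D^{1/2} W_i^{-1} D^{1/2}
  q11 <- t0^2 * w22 / detW
  q12 <- -t0 * t1 * w12 / detW
  q22 <- t1^2 * w11 / detW
  ## A = sum_i (S - S Q S) = X' V0^{-1} X ; c = sum_i (u - S Q u)
  Sq11 <- st$s11 * q11 + st$s12 * q12; Sq12 <- st$s11 * q12 + st$s12 * q22
  Sq21 <- st$s12 * q11 + st$s22 * q12; Sq22 <- st$s12 * q12 + st$s22 * q22
  a11 <- st$s11 - (Sq11 * st$s11 + Sq12 * st$s12)
  a12 <- st$s12 - (Sq11 * st$s12 + Sq12 * st$s22)
  a22 <- st$s22 - (Sq21 * st$s12 + Sq22 * st$s22)
  c1 <- st$u1 - (Sq11 * st$u1 + Sq12 * st$u2)
  c2 <- st$u2 - (Sq21 * st$u1 + Sq22 * st$u2)
  d <- st$yy - (st$u1 * (q11 * st$u1 + q12 * st$u2) +
                st$u2 * (q12 * st$u1 + q22 * st$u2))
  A <- matrix(c(sum(a11), sum(a12), sum(a12), sum(a22)), 2L)
  cc <- c(sum(c1), sum(c2))
  beta <- tryCatch(solve(A, cc), error = function(e) NULL)
  if (is.null(beta)) return(structure(Inf, beta = c(NA, NA), s2 = NA))
  rss <- max(sum(d) - sum(cc * beta), 1e-300)  # r' V0^{-1} r at GLS beta
  N <- st$N; p <- 2L
  if (reml) {
    s2 <- rss / (N - p)
    dev <- sum(log(detW)) +
      as.numeric(determinant(A, logarithm = TRUE)$modulus) +
      (N - p) * log(2 * pi * s2) + (N - p)
  } else {
    s2 <- rss / N
    dev <- sum(log(detW)) + N * log(2 * pi * s2) + N
  }
  out <- structure(dev, beta = beta, s2 = s2)
  if (keep) {
    attr(out, "woodbury") <- list(q11 = q11, q12 = q12, q22 = q22)
  }
  out
}

lmm_optimize <- function(st, reml, random_slope, starts) {
  npar <- if (random_slope) 2L else 1L
  obj <- function(th) as.numeric(lmm_profiled_deviance(th, st, reml = reml))
  best <- NULL
  for (s in starts) {
    s <- s[seq_len(npar)]
    o <- stats::optim(s, obj, method = "L-BFGS-B",
                      lower = rep(0, npar), upper = rep(1e4, npar),
                      control = list(factr = 1e4, maxit = 500L))
    if (o$convergence != 0L && !is.finite(o$value))
      stop("mixed-model optimisation failed to converge: ", o$message)
    if (is.null(best) || o$value < best$value - 1e-10) best <- o
  }
  list(theta = best$par, deviance = best$value)
}

lmm_finish <- function(st, theta, reml, group_levels) {
  dev <- lmm_profiled_deviance(theta, st, reml = reml, keep = TRUE)
  beta <- attr(dev, "beta"); s2 <- attr(dev, "s2")
  wb <- attr(dev, "woodbury")
  t0 <- theta[1]; t1 <- if (length(theta) > 1L) theta[2] else 0
  ## BLUPs: b_i = D0 (h_i - S_i Q_i h_i), h_i = Z_i'(y_i - X_i beta)
  h1 <- st$u1 - (st$s11 * beta[1] + st$s12 * beta[2])
  h2 <- st$u2 - (st$s12 * beta[1] + st$s22 * beta[2])
  Qh1 <- wb$q11 * h1 + wb$q12 * h2
  Qh2 <- wb$q12 * h1 + wb$q22 * h2
  SQh1 <- st$s11 * Qh1 + st$s12 * Qh2
  SQh2 <- st$s12 * Qh1 + st$s22 * Qh2
  b0 <- t0^2 * (h1 - SQh1)
  b1 <- t1^2 * (h2 - SQh2)
  singular <- any(theta < 1e-4)
  structure(list(
    beta = c(intercept = unname(beta[1]), slope = unname(beta[2])),
    sd_intercept = t0 * sqrt(s2),
    sd_slope = t1 * sqrt(s2),
    sigma = sqrt(s2),
    theta = theta,
    logLik = -as.numeric(dev) / 2,
    deviance = as.numeric(dev),
    reml = reml,
    n_obs = st$N,
    n_groups = st$G,
    singular = singular,
    ranef = data.frame(group = group_levels, intercept_dev = b0,
                       slope_dev = b1, stringsAsFactors = FALSE)
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), %d obs in %d groups\n",
              if (x$reml) "REML" else "ML", x$n_obs, x$n_groups))
  cat(sprintf("  fixed: intercept %.4f, slope %.4f\n",
              x$beta[1], x$beta[2]))
  cat(sprintf("  random SDs: intercept %.4f, slope %.4f; residual %.4f%s\n",
              x$sd_intercept, x$sd_slope, x$sigma,
              if (x$singular) " (singular)" else ""))
  cat(sprintf("  logLik %.4f\n", x$logLik))
  invisible(x)
}
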