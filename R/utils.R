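#' @keywords internal
"_PACKAGE"

## Clip values to a closed interval.
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Deterministic per-stage seed derivation: every randomized stage draws its
## seed from the root seed plus a named offset, so stages are decoupled
## (adding permutations to one stage never shifts another stage's stream).
## Kept below 2^31 - 1 so the value is a valid R integer seed.
stage_seed <- function(seed, stage) {
  offsets <- c(
    lesions = 101L, outcomes = 211L, longitudinal = 307L,
    lsm = 401L, svr = 503L, recovery = 601L, demographics = 701L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 48271 + off * 9973) %% 2147483647)
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("lsmrecov_config_error", "error")))
}

validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("lsmrecov_validation_error", "error")))
}

## Format an mm coordinate triple the way neuroimaging papers print peaks.
format_mm <- function(xyz) paste(formatC(xyz, format = "f", digits = 0), collapse = ", ")
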