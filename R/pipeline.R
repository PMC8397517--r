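#' Configuration for an end-to-end analysis run
#'
#' Exactly one of `simulate` (a [simulation_config()]) or `paths` (a named
#' list with `lesion_dir`, `cohort_csv` and optionally `longitudinal_csv`)
#' must be supplied. The root seed propagates deterministically to every
#' stage through named sub-streams, so adding permutations to one stage
#' never changes another stage's draws.
#'
#' @param simulate A [simulation_config()], or `NULL` when reading data.
#' @param paths Named list of input paths, or `NULL` when simulating.
#' @param design A [design_spec()] for the univariate analysis.
#' @param svr An [svr_spec()] for the multivariate analysis.
#' @param recovery List: `families` (names or `"all"`), `params` (optional
#'   fixed `c(scale=, shape=)`), `grid_size`.
#' @param stages Stages to run, a subset of
#'   `c("lsm", "svr", "recovery", "demographics")`.
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @param seed Root seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            design = design_spec(), svr = svr_spec(),
                            recovery = list(families = "all",
                                            params = NULL, grid_size = 16L),
                            stages = c("lsm", "svr", "recovery",
                                       "demographics"),
                            out_dir = NULL, seed = 1L) {
  if (is.null(simulate) == is.null(paths))
    config_error("exactly one of 'simulate' or 'paths' must be given")
  if (!is.null(simulate) && !inherits(simulate, "simulation_config"))
    config_error("'simulate' must be a simulation_config")
  bad <- setdiff(stages, c("lsm", "svr", "recovery", "demographics"))
  if (length(bad)) config_error(paste("unknown stage(s):",
                                      paste(bad, collapse = ", ")))
  structure(list(simulate = simulate, paths = paths, design = design,
                 svr = svr, recovery = recovery, stages = stages,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the cohort, then runs the requested stages:
#' univariate LSM, SVR LSM, recovery-curve fitting with BIC family
#' selection, and the demographic regressions. Stage failures are caught and
#' surfaced with the stage name while completed stage outputs are kept.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_bundle`: list with `cohort`, `lesions`,
#'   `longitudinal`, per-stage results (`lsm`, `svr`, `recovery`,
#'   `demographics`), `errors` (named list of stage error messages) and
#'   `manifest` (seeds, config, file hashes when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    cfg$seed <- seed
    lesions <- generate_lesions(cfg)
    cohort <- generate_outcomes(lesions, cfg)
    longitudinal <- generate_longitudinal(cfg)
    demo_long <- attr(longitudinal, "demographics")
  } else {
    p <- config$paths
    if (is.null(p$lesion_dir) || is.null(p$cohort_csv))
      config_error("paths must name lesion_dir and cohort_csv")
    files <- sort(list.files(p$lesion_dir, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    lesions <- lapply(files, read_lesion_volume)
    cohort <- read_cohort_table(p$cohort_csv)
    longitudinal <- if (!is.null(p$longitudinal_csv))
      read_longitudinal_table(p$longitudinal_csv) else NULL
    demo_long <- if (!is.null(p$demographics_csv))
      utils::read.csv(p$demographics_csv, stringsAsFactors = FALSE) else NULL
  }

  bundle <- list(cohort = cohort, lesions = lesions,
                 longitudinal = longitudinal, errors = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bundle$errors[[name]] <<- conditionMessage(e)
      message(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      NULL
    })
  }

  if ("lsm" %in% config$stages) {
    design <- config$design
    design$seed <- stage_seed(seed, "lsm")
    bundle$lsm <- run_stage("lsm", run_univariate_lsm(cohort, lesions, design))
  }
  if ("svr" %in% config$stages) {
    svr <- config$svr
    svr$seed <- stage_seed(seed, "svr")
    bundle$svr <- run_stage("svr",
                            run_svr_lsm(cohort, lesions, svr, config$design))
  }
  if ("recovery" %in% config$stages && !is.null(longitudinal)) {
    rec <- config$recovery
    fams <- rec$families
    if (identical(fams, "all")) fams <- compression_families()
    bundle$recovery <- run_stage("recovery", {
      filtered <- filter_recovery_cohort(longitudinal)
      select_best_family(filtered, families = fams, params = rec$params,
                         grid_size = rec$grid_size %||% 16L)
    })
  }
  if ("demographics" %in% config$stages) {
    bundle$demographics <- run_stage("demographics", {
      out <- list(outcome = outcome_regression(cohort, config$design$score))
      if (!is.null(bundle$recovery) && !is.null(demo_long)) {
        slopes <- extract_slopes(bundle$recovery[[1L]])
        out$slopes <- slope_regression(slopes, demo_long)
      }
      out
    })
  }

  bundle$manifest <- list(
    seed = seed,
    stage_seeds = list(lsm = stage_seed(seed, "lsm"),
                       svr = stage_seed(seed, "svr"),
                       recovery = stage_seed(seed, "recovery")),
    stages = config$stages,
    design = unclass(config$design),
    svr = unclass(config$svr),
    simulated = !is.null(config$simulate),
    n_patients = nrow(cohort),
    package_version = as.character(utils::packageVersion("lsmrecov"))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    ov <- compute_overlay(lesions)
    pov <- file.path(config$out_dir, "overlay.nii.gz")
    write_overlay(ov, pov); written <- c(written, pov)
    pc <- file.path(config$out_dir, "cohort.csv")
    write_cohort_table(cohort, pc); written <- c(written, pc)
    if (!is.null(longitudinal)) {
      pl <- file.path(config$out_dir, "longitudinal.csv")
      write_longitudinal_table(longitudinal, pl); written <- c(written, pl)
    }
    if (!is.null(bundle$lsm))
      written <- c(written, write_stat_map(bundle$lsm, config$out_dir, "tmap"))
    if (!is.null(bundle$svr))
      written <- c(written, write_stat_map(bundle$svr, config$out_dir, "wmap"))
    bundle$manifest$files <- as.list(tools::md5sum(written))
    pm <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(bundle$manifest, pm, auto_unbox = TRUE, digits = NA)
    rep <- render_report(structure(bundle, class = "pipeline_bundle"))
    writeLines(rep, file.path(config$out_dir, "report.txt"))
  }
  structure(bundle, class = "pipeline_bundle")
}

#' Render a human-readable summary of a pipeline run
#'
#' One text document per run: cohort summary, univariate and SVR maps in the
#' standard reporting format (statistic max, peak mm coordinate, cluster
#' size, threshold), the BIC family table, and recovery milestones for the
#' selected curve. Stages that were not run are marked as such.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  ln <- c("Lesion-symptom mapping and recovery report",
          "===========================================", "")
  ln <- c(ln, sprintf("Cohort: %d patients; mean lesion volume %.1f cc",
                      nrow(bundle$cohort),
                      mean(bundle$cohort$lesion_volume_cc)), "")
  map_block <- function(sm, label) {
    if (is.null(sm)) return(c(sprintf("%s: not run", label), ""))
    hdr <- sprintf("%s (threshold %.3f, alpha %g, %d perms):", label,
                   sm$critical_t, sm$spec$alpha, sm$spec$n_perm)
    if (is.null(sm$peak))
      return(c(hdr, "  no suprathreshold voxels", ""))
    c(hdr,
      sprintf("  %s-max = %.2f at %s, cluster size = %d, clusters = %d",
              sm$statistic, sm$peak$stat, format_mm(sm$peak$mm),
              if (nrow(sm$clusters)) sm$clusters$size[1] else 0L,
              nrow(sm$clusters)), "")
  }
  ln <- c(ln, map_block(bundle$lsm, "Univariate LSM"))
  ln <- c(ln, map_block(bundle$svr, "Multivariate (SVR) LSM"))
  if (is.null(bundle$recovery)) {
    ln <- c(ln, "Recovery modelling: not run", "")
  } else {
    tab <- summary(bundle$recovery)
    ln <- c(ln, "Recovery modelling, BIC by time-compression family:")
    ln <- c(ln, sprintf("  %-16s BIC = %8.2f  (scale %.3g%s)", tab$family,
                        tab$bic, tab$scale,
                        ifelse(is.na(tab$shape), "",
                               sprintf(", shape %.3g", tab$shape))))
    best <- bundle$recovery[[1L]]
    ms <- recovery_milestones(best, c(12, 36))
    ln <- c(ln, sprintf("  best: %s, slope %.2f (random-slope SD %.2f)",
                        best$family, best$slope, best$sd_slope))
    ln <- c(ln, sprintf("  fraction of improvement by %d months: %.0f%%",
                        ms$months, 100 * ms$fraction), "")
  }
  if (is.null(bundle$demographics)) {
    ln <- c(ln, "Demographic regressions: not run", "")
  } else {
    ln <- c(ln, "Demographic regressions:",
            utils::capture.output(print(bundle$demographics$outcome)))
    if (!is.null(bundle$demographics$slopes))
      ln <- c(ln, utils::capture.output(print(bundle$demographics$slopes)))
    ln <- c(ln, "")
  }
  if (length(bundle$errors))
    ln <- c(ln, "Stage errors:",
            sprintf("  %s: %s", names(bundle$errors),
                    unlist(bundle$errors)), "")
  ln
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
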