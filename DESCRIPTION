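Package: lsmrecov
Title: Lesion-Symptom Mapping and Longitudinal Recovery Modelling for
    Stroke Aphasia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating left-hemisphere stroke lesions to auditory
    comprehension outcomes and for modelling the time course of longitudinal
    recovery. Provides univariate voxel-wise lesion-symptom mapping with
    covariate adjustment and maximum-statistic permutation thresholding,
    multivariate lesion-symptom mapping via support vector regression with
    lesion-size normalisation, survival-curve style time compression of
    months post-onset fitted with linear mixed-effects models and selected
    by BIC, demographic regressions on outcome scores and recovery slopes,
    and a synthetic cohort generator that emulates the statistical structure
    of retrospective aphasia datasets so that every stage of the pipeline can
    be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lme4,
    kernlab,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
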