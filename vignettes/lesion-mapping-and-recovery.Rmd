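---
title: "Lesion-symptom mapping and longitudinal recovery modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-symptom mapping and longitudinal recovery modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsmrecov)
```

## Scope

`lsmrecov` implements two complementary analyses of auditory-comprehension
deficits after left-hemisphere stroke, plus the infrastructure to validate
them without patient data:

1. **Lesion-symptom mapping (LSM).** Voxel-wise association between lesion
   status and a behavioral score, with covariate adjustment and
   familywise-error control by maximum-statistic permutation; and a
   multivariate counterpart using support vector regression (SVR) over all
   voxels jointly.
2. **Recovery-curve modelling.** Longitudinal comprehension scores are
   modelled on a compressed time axis — a survival-style CDF of months
   post-onset (MPO) — using linear mixed-effects models, with the
   compression family selected by BIC and per-patient recovery slopes
   extracted for downstream regressions.

Because clinical stroke databases are rarely shareable, the package ships a
synthetic cohort generator whose defaults emulate the cohort structure these
analyses assume; every pipeline stage is exercised against it in the test
suite.

## Univariate LSM

At voxel $v$ with lesion indicator $\ell_{iv}$ for patient $i$, the model is

$$ y_i = \beta_0 + \beta_\ell \ell_{iv} + \gamma' z_i + \varepsilon_i $$

with nuisance covariates $z_i$ (defaults: age, gender, months post-stroke,
overall aphasia severity as WAB AQ, and lesion volume). The reported map is
the t statistic of $\beta_\ell$, signed so that damage predicting a *lower*
score is positive. Only voxels lesioned in at least `min_overlap = 5`
patients (and intact in at least one) are analyzed; this guards against
regression estimates driven by a handful of cases. Internally the score and
all lesion columns are residualised against the covariates once
(Frisch–Waugh), reducing the whole map to two matrix products; the result is
identical to per-voxel multiple regression, which the tests verify against
an independent normal-equations oracle at 1e-10 relative tolerance.

**Permutation thresholding.** The critical t is the upper $1-\alpha$
quantile (ceiling-rank order statistic, the conservative choice) of the
null distribution of the whole-map *maximum* t over `n_perm` permutations
(default 10,000, $\alpha = 0.05$). With nuisance covariates, raw score
shuffling does not respect exchangeability, so the default scheme is
Freedman–Lane: residuals of the covariate-only model are permuted, the
covariate fit is re-added, and the full model recomputed. Raw-score
permutation remains available (`scheme = "raw"`); on the null synthetic
cohorts both control the familywise error rate within binomial tolerance
of $\alpha$, which the acceptance suite checks over 200 null cohorts.

**Clusters and peaks.** Suprathreshold voxels are partitioned into
26-connected components (the common neuroimaging default; the choice is
config-free but documented here as a convention, not a finding). Peaks are
reported in template mm via the volume affine, with 0-based voxel indexing;
ties are broken by ascending linear index so outputs are deterministic.

## Multivariate (SVR) LSM

All analyzable voxels jointly enter an $\epsilon$-SVR of the score on the
lesion features. Defaults follow the multivariate LSM literature: RBF
kernel, $C = 30$, $\gamma = 5$, $\epsilon = 0.1$, and direct total lesion
volume control (dTLVC) — each patient's binary row scaled by
$1/\sqrt{\text{lesion size}}$ so every row has unit sum of squares. The
voxel weight map is the back-projection $w_v = \sum_i \alpha_i x_{iv}$ of
the dual solution (for the linear kernel this is exactly the primal weight
vector), with the same deficit-positive sign convention. Covariates are
handled by residualising the score against them before the fit. Weights are
*not* rescaled to pseudo-t values; the raw back-projected weights are
thresholded by their own maximum-statistic permutation null, the direct
analogue of the univariate procedure. The linear-kernel path is validated
against an independent quadratic-programming solution of the SVR dual to
six significant figures.

Two caveats, verified empirically in the tests: weight magnitudes track
univariate |t| only in rank (Spearman), and exact scale-equivariance of the
thresholded voxel set holds when $\epsilon = 0$ and $C$ scales with the
scores — with a fixed $\epsilon$ tube the solution is only approximately
scale-equivariant.

## Time compression and mixed models

Recovery is fast early and slow late, so score is modelled as linear in a
compressed time $f(\text{MPO}) \in [0, 1)$ rather than in MPO itself:

$$ y_{ik} = \beta_0 + \beta_1 f(\text{MPO}_{ik}) + u_{0i} + u_{1i}
   f(\text{MPO}_{ik}) + \varepsilon_{ik}, $$

with independent random intercepts and slopes per patient. $\beta_1 + u_{1i}$
is patient $i$'s recovery slope: score points gained over the whole course
of recovery. Ten candidate families are provided (see `?compress_time` for
the exact parameterisations; the family names are conventional but their
formulas are stated explicitly because survival parameterisations vary
across software). The selected family here is the log-logistic
$f(t) = 1/(1 + (t/a)^{-b})$ with scale $a = 8$ months and shape $b = 0.9$,
under which half of the asymptotic improvement is reached by 8 months,
roughly 60% by 12 months and 80% by 36 months.

**Estimation.** The mixed model is fitted by direct optimisation of the
profiled deviance: fixed effects and the residual variance are profiled out
analytically, leaving a bounded 2-parameter optimisation over the relative
random-effect SDs. Because the per-patient random design is two columns,
each objective evaluation reduces to vectorised 2×2 Woodbury algebra on
per-group sufficient statistics — an evaluation costs O(patients), which
makes profiling the transformation parameters over a 16×16 log-spaced grid
with Nelder–Mead refinement (relative tolerance 1e-6, refinement boxed to
the grid range extended four-fold) affordable. Fits are deterministic
without any seed. The test suite validates log-likelihoods, fixed effects,
variance components and BLUPs against `lme4` on random instances.

**Why ML and not REML for selection.** `lmm_fit()` defaults to REML, but
`fit_family()` and `select_best_family()` use maximum likelihood: the fixed
design $[1, f(\text{MPO})]$ changes with the transformation parameters and
across families, and REML likelihoods are not comparable across
fixed-effects designs. BIC is $-2\ell + k\log N$ with $N$ the number of
observations (the standard choice for longitudinal model comparison) and
$k$ counting two fixed effects, the variance parameters, and any *fitted*
transformation parameters; fixing the transformation a priori
(`params = c(scale = 8, shape = 0.9)`) removes those from $k$. Whether the
original analyses fitted or fixed the transformation is not recoverable, so
both modes are exposed.

**Slope SD.** The reported between-patient slope SD of 0.60 is treated as
the random-slope SD (not the standard error of the fixed slope) both in the
generator defaults and in interpretation; this is an explicit reading of an
ambiguous quantity.

## The synthetic cohort generator

The generator's defaults are the study conditions the analyses assume, at
desk scale:

* **Grid.** 32×40×32 voxels at 4 mm (not 1 mm template resolution); all
  operations are grid-agnostic, and the affine places the grid centre at
  the mm origin with low *i* mapping to negative x (left hemisphere).
* **Lesions.** Randomised 26-connected region growing from seeds inside an
  elliptical vascular-territory mask, biased (weight 1 vs 0.15) to stay in
  territory — a cheap stand-in for middle-cerebral-artery topology, not an
  anatomical simulation. Target volumes are log-normal with mean 121.8 cc
  and `sdlog = 0.4` (dispersion is the package's choice; only the mean is
  an emulated quantity). Growth stops exactly at the target count, so
  realised volumes match the draw.
* **Cross-sectional scores.** Each subtest is a base level minus
  `effect_size = 30` points per unit fractional damage to a designated
  critical region (a small sphere in the simulated posterior temporal
  territory), plus centred covariate effects and Gaussian noise
  (`residual_sd = 5`), clipped to the score range. Covariate marginals:
  age ~ N(61, 11), education 12–22, 79% male, AQ ~ N(71, 28) clipped.
  Covariates are drawn independently of the lesions, so with
  `effect_size = 0` scores carry no lesion information — the null case used
  for familywise-error validation.
* **Longitudinal block.** 44 patients by default; 2–6 sessions with mean
  ~2.7; session times log-uniform over 1–220 months with successive
  sessions forced ≥ 1 month apart; slopes ~ N(3.71, 0.60); baselines
  ~ N(3.5, 1.8) (chosen so that initial overall scores centre near 6 on the
  0–10 scale, matching the emulated cohort); within-patient residual SD 1.0
  on the 0–10 scale (the source analyses do not state this quantity; it is
  exposed in the config); first-session scores < 9 enforced by resampling
  the baseline; scores clipped to [0, 10] (ceiling effects are modelled by
  clipping only — no censoring-aware likelihood).

What passing tests on this generator do *not* show: real lesions are not
region-grown blobs (spatial covariance of real lesion anatomy is far
richer), real covariates correlate with lesion size and location, and real
ceiling behaviour is more structured than clipping. The generator validates
the statistical machinery — error control, oracle equivalence, parameter
recovery, localisation — not anatomical claims.

## Numerical choices and degenerate inputs

* Voxels with no lesion contrast after residualisation (constant, or
  collinear with covariates) are flagged not-analyzed (`NA`), never zero.
* If both the effect numerator and the residual variance vanish (all scores
  equal), the voxel t is defined as 0.
* Variance components are optimised on the boundary-closed scale, so
  singular fits (a variance estimated at zero) are flagged, not fatal.
* An SVR in which every score lies inside the $\epsilon$ tube has no
  support vectors; the weight map is defined as identically zero.
* Permutation thresholds use the ceiling-rank order statistic;
  `n_perm * alpha >= 1` is enforced.
* All randomised operations take explicit seeds; pipeline stages derive
  named sub-seeds from one root seed, so stages are decoupled.

## Known limitations

* Peak coordinates mislocalise by a voxel or two when lesions are spatially
  contiguous: voxels just outside a small critical region are almost
  perfectly correlated with damage to it, so the global peak can tie onto a
  neighbour of the true region even when the suprathreshold cluster covers
  it. Cluster overlap, not exact peak containment, is the robust
  localisation readout for compact targets.
* With one estimated slope per patient, the slope-on-demographics
  "mixed-effects" specification degenerates; it is implemented as
  (optionally weighted) least squares, which is the well-posed reading.
* At realistic noise (residual SD 1.0, ~2.7 sessions/patient), several
  compression families are near-equivalent: lomax, weibull and log-logistic
  differ by fractions of a log-likelihood unit, and one-parameter families
  gain a $\log N$ BIC advantage per parameter saved. BIC ranks among these
  near-twins are therefore unstable — model selection identifies a *class*
  of adequate compressions rather than a unique family, and the package's
  BIC table should be read that way. Parameter recovery *within* the
  selected family is accurate (validated at n = 500).
* Test-suite problem sizes (desk-scale grids, 200–500 permutations, 20-seed
  replicates) are the package's validation scale; production analyses
  should use the full 10,000-permutation defaults.

## Reading the outputs

`run_univariate_lsm()` prints in the field's reporting format — e.g.
`t-max = 6.97 at -60, -38, -14, cluster size = 4583, t-threshold = 4.46`
would mean: the largest voxel t, its template mm coordinate, the size of
the largest suprathreshold 26-connected component, and the permutation
critical value. `select_best_family()` prints the BIC table ascending;
`recovery_milestones()` turns a fit into "fraction of total improvement by
month m", the clinically interpretable summary of the compressed scale.
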