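---
title: "Estimating white-matter heritability from twin DTI data"
author: "twinDTI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating white-matter heritability from twin DTI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinDTI)
```

## The problem

Diffusion tensor imaging summarizes white-matter microstructure with four
scalar metrics per voxel — fractional anisotropy (FA), mean, axial and
radial diffusivity (MD, AD, RD) — and the classical twin design asks how
much of the between-person variance in those metrics is genetic.
Monozygotic (MZ) co-twins share essentially all segregating genetic
variants; dizygotic (DZ) co-twins share on average half of the additive and
a quarter of the dominance genetic variance. Comparing within-pair
correlations across the two zygosity groups therefore identifies the
standardized variance components

* **A** — additive genetic effects,
* **C** — environment shared within a family, or
* **D** — non-additive (dominance/epistatic) genetic effects,
* **E** — individual-specific environment, which also absorbs measurement
  error,

under the constraint A + C + D + E = 1. C and D are confounded for twins
reared together, so one of the two fully parameterized models is fitted per
trait: ACE or ADE. We report heritability as G = A under ACE (narrow sense)
and G = A + D under ADE (broad sense).

`twinDTI` implements the full analysis path: regional extraction from
skeletonised 4D maps, scanner harmonization, age/sex adjustment, twin
correlations, and constrained maximum-likelihood variance decomposition —
plus a synthetic cohort generator with known truth so every stage can be
validated without imaging data.

## Model and estimation

The expected within-pair correlations are `r_mz = A + C + D` and
`r_dz = A/2 + C + D/4`. With two observed correlations and the unit-sum
constraint, the fully parameterized models are exactly identified, and the
method-of-moments (Falconer) solutions are closed-form:

* ACE: `A = 2(r_mz − r_dz)`, `C = 2 r_dz − r_mz`, `E = 1 − r_mz`
* ADE: `A = 4 r_dz − r_mz`, `D = 2 r_mz − 4 r_dz`, `E = 1 − r_mz`

These can be negative, which is biologically inadmissible, so
`fitBiometricModel()` instead maximizes the Gaussian likelihood of the two
2×2 within-pair correlation matrices (group weights `n − 1`) subject to
`A, C, D ≥ 0` and `E ≥ 0.001`. The floor on E reflects that E contains
measurement error and cannot vanish. Because the model is exactly
identified, an interior optimum reproduces the observed correlations and
coincides with the Falconer solution; the package tests enforce agreement
to 1e-6. When the unconstrained solution is inadmissible the optimizer
pins the offending component at its bound (e.g. a negative MZ correlation
pins A at 0 and the fit degenerates to a weighted estimate of C).

Numerically, the fit runs a log-barrier quasi-Newton search
(`constrOptim`, analytic gradient) from five fixed starting points,
followed by an active-set polish that re-optimizes each plausible boundary
configuration without the barrier and keeps the best candidate; ties are
broken toward the smaller A. The candidate set includes the
method-of-moments point whenever it is feasible, which guarantees the
exact global optimum in the interior case. Only point estimates are
produced: with cohorts of this size the sampling error of variance
components is large, and interval estimation is out of scope.

Which model to fit is itself undetermined by two correlations; the package
uses the conventional signature `r_dz < r_mz / 2 → ADE`, otherwise ACE
(ties to ACE, preferring the more commonly interpretable shared-environment
parameterization). Applied to the bundled published correlation table this
rule reproduces the published model assignment in every row.

## Twin correlations

`twinCorrelations()` uses the double-entry Pearson estimator: each pair
contributes both orderings, making the estimate invariant to arbitrary twin
labeling and equal to the ANOVA intraclass correlation. Values are first
residualized on age and sex (`adjustAgeSex()`) with a single linear model
pooled over zygosity groups — the stratification is not identifiable from
the design, and pooling keeps the adjustment stable at these sample sizes.
Opposite-sex DZ pairs are retained because sex is regressed out before
correlating. Pairs missing a member's value for a region/metric are dropped
pairwise for that cell; groups with fewer than three complete pairs yield a
missing estimate rather than a fragile one.

MZ and DZ correlations are compared with a one-sided Fisher z test
(`n − 3` denominators). The published p-values were evidently computed from
unrounded correlations, so refitting from the printed 2-decimal values
reproduces their magnitude but not every fourth decimal; the package does
not force agreement.

## Regional extraction and harmonization

`extractRegionalMeans()` consumes skeletonised 4D maps (subject along the
fourth dimension) and an integer label atlas on the same voxel grid — no
resampling is attempted, matching the standard-space outputs of a
TBSS-style pipeline and the JHU ICBM-DTI-81 atlas. Voxels with a value of
exactly 0 are outside the skeleton projection (the projection writes
literal zeros) and are excluded before averaging; a region with no
remaining voxel for a subject becomes a flagged missing cell and is never
imputed. Six brainstem/cerebellar regions with chronically poor skeleton
coverage (`defaultRegionExclusions()`) are dropped, leaving the 42
analysable regions; bilateral regions are kept separate (`_L`/`_R`).

Scanner differences are removed with ComBat: parametric empirical-Bayes
location/scale harmonization at the regional level, with age and sex
specified as biological covariates to preserve. The implementation
separates `fitComBat()` from `applyComBat()` so the model (grand means,
pooled variances, covariate coefficients, EB-shrunk per-batch location and
scale, prior hyperparameters) can be serialized to JSON and audited.
Harmonization is per metric; whether to pool metrics is not determined by
the method and per-metric fitting keeps the feature set homogeneous. EB
updates iterate to a relative change below 1e-4 (cap 100 iterations).
Missing cells are excluded feature-wise from estimation and pass through
unchanged. The test suite checks the implementation against the reference
implementation in `sva` to 1e-6 on complete data, and checks the
covariate-preservation and batch-removal properties on synthetic cohorts.

## The synthetic cohort generator

`twinSimConfig()` + `buildRoster()` + `simulateTwinMetrics()` emulate the
study conditions end to end:

* 33 MZ and 48 DZ pairs by default (10 DZ pairs opposite-sex); an initial
  roster can be larger with exclusions applied in the cascade order
  psychiatric → missing MRI → low-quality DTI.
* ages shared within pair, truncated-normal with mean 16.7, SD 6.1 years
  on 9–32 (an adolescent-heavy population-registry profile);
* true variance components per region and metric default to the published
  regional estimates (`referenceComponents()`), so simulated cohorts have
  realistic heterogeneity across the 42 regions;
* trait scales are physiologically plausible rather than estimated: FA
  around 0.5 (SD 0.02, clipped to [0, 1]), MD/AD/RD around
  0.8/1.2/0.6 ×10⁻³ mm²/s; age slopes of a few 10⁻³ FA units (and a few
  10⁻⁶ mm²/s) per year and small additive sex offsets;
* two scanners sampled 47:34 per pair; the second applies a +0.3
  residual-SD location shift and a 1.2× residual scale — exactly the
  location/scale structure ComBat models.

Latent factors are standard normal, scaled by √A, √C, √D, √E; the DZ
additive factor is √(1/2)·shared + √(1/2)·unique and the dominance factor
√(1/4)·shared + √(3/4)·unique, which yields the biometric covariance
algebra exactly, so the generator's population correlations are
`A + C + D` (MZ) and `A/2 + C + D/4` (DZ) by construction. The generator
draws Gaussian traits; real regional DTI values are only approximately
Gaussian (the twin model assumes normality but data need not comply), and
the generator does not emulate registration error, skeleton-projection
artefacts, spatial correlation between regions, or age-by-genotype
interactions. Passing tests therefore validate the estimators under the
model's own assumptions, not the upstream imaging chain.

`simulateSkeletonVolumes()` additionally builds small labeled volumes whose
labeled voxels scatter around known regional values (background exactly
zero), which is how the extraction stage is tested against a brute-force
voxel loop.

## Worked example

```{r example}
cfg <- twinSimConfig(nMZ = 33, nDZ = 48, seed = 42)
roster <- buildRoster(cfg)
cohort <- simulateTwinMetrics(roster, cfg)
cohort

harmonized <- harmonizeMetrics(cohort)$data
resid <- adjustAgeSex(harmonized)
cors <- correlationTable(twinCorrelations(resid))
report <- fitComponentsTable(cors)
head(report[report$metric == "FA",
            c("region", "r_mz", "r_dz", "model", "A", "C", "D", "G", "E")])
```

Refitting from the bundled published correlation table instead of a
simulation:

```{r published}
ref <- referenceTwinCorrelations()
scc <- ref[ref$region == "sCC" & ref$metric == "FA", ]
fit <- fitBiometricModel(scc$r_mz, 33, scc$r_dz, 48)
fit
```

## Numerical conventions and edge cases

* Report rounding is half-up to 2 decimals (`roundHalfUp()`), the
  convention of the published tables; totals are printed as the rounded
  sum and may read 1.00 while rounded addends sum to 0.99–1.01.
* Correlations of |r| = 1 are rejected (infinite Fisher transform /
  singular correlation matrix) rather than clamped.
* The demographic chi-square compares pair sex composition
  (male–male / female–female / opposite-sex) across zygosity without
  continuity correction; the age comparison is an unpaired Student t-test.
  With zero age variance the t statistic is defined as 0.
* Pipeline runs are deterministic: all randomness flows from the single
  configured seed, and the run manifest records an MD5 for every artifact,
  so a rerun must be bit-identical.

## Problem sizes used in validation

The test suite simulates up to 10,000 pairs per zygosity for checking the
generator's population correlations (tolerance ±0.02–0.03), uses 2,000
pairs per zygosity over 20 seeds for full-pipeline parameter recovery
(mean absolute component error below 0.05 at truth A = 0.5, C = 0.2,
E = 0.3), and validates the interior ML/Falconer equivalence on 1,000
random correlation pairs. Extraction oracles run on ≤ 8³-voxel fixtures
with ≤ 6 subjects. These sizes make the statistical tolerances sharp while
keeping a full check run around a minute on one core.

## Known limitations

* No raw-data structural-equation fitting (means models, saturated-model
  assumption checks), no sex-limitation or developmental moderation
  models, no AE/CE/E sub-model comparison — the fully parameterized
  ACE/ADE point estimates are the deliverable.
* No confidence intervals for components; with 33/48 pairs they would be
  wide, and the intended use is descriptive regional profiling.
* Harmonization assumes the batch effect is location/scale within each
  feature; site-by-covariate interactions are not modeled.
* Upstream imaging stages (tensor fitting, registration, skeleton
  projection) are out of scope; the package starts at eigenvalue maps or
  skeletonised metric maps.
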