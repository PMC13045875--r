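#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData "colData<-" "assay<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom stats coef cor lm lm.fit median optim optimize constrOptim
#'   pchisq pnorm qnorm residuals rnorm runif sd setNames var
#'   complete.cases model.matrix chisq.test t.test na.exclude aggregate
#' @importFrom utils read.csv write.csv packageVersion head
NULL

VALID_METRICS <- c("FA", "MD", "AD", "RD")
VALID_MODELS <- c("ACE", "ADE")

#' Simulation configuration for a synthetic twin cohort
#'
#' An S4 container holding everything the synthetic-cohort generator needs:
#' pair counts, per-region/per-metric true variance components, covariate
#' effects, scanner batch effects and the random seed. Construct with
#' [twinSimConfig()], which supplies defaults emulating an 81-pair adolescent
#' twin cohort scanned on two Philips 3T systems.
#'
#' @slot nMZ,nDZ Numbers of monozygotic and dizygotic pairs.
#' @slot components `data.frame` with columns `region`, `metric`, `model`
#'   (`"ACE"` or `"ADE"`), `A`, `C`, `D`, `E`: standardized true variance
#'   fractions per region and metric. Each row must satisfy the biometric
#'   normalization A + C + D + E = 1 (within 0.01) with all fractions
#'   non-negative, `E > 0`, `C = 0` under ADE and `D = 0` under ACE.
#' @slot ageRange Length-2 numeric, admissible ages in years.
#' @slot ageMean,ageSD Mean and SD of the (truncated normal) age distribution.
#' @slot oppositeSexFraction Fraction of DZ pairs that are opposite-sex.
#' @slot metricBase,metricSD Named numerics: trait mean and residual SD per
#'   metric, in metric units (FA dimensionless, diffusivities in mm^2/s).
#' @slot ageEffect,sexEffect Named numerics: linear age slope (units/year) and
#'   additive male offset per metric.
#' @slot scanners Character vector of scanner/batch labels.
#' @slot scannerProb Sampling probability of each scanner (per pair).
#' @slot batchShift,batchScale Named numerics per scanner: additive location
#'   shift (in residual-SD units) and multiplicative residual scale.
#' @slot seed Integer random seed.
#' @export
setClass("TwinSimConfig", representation(
  nMZ = "numeric", nDZ = "numeric",
  components = "data.frame",
  ageRange = "numeric", ageMean = "numeric", ageSD = "numeric",
  oppositeSexFraction = "numeric",
  metricBase = "numeric", metricSD = "numeric",
  ageEffect = "numeric", sexEffect = "numeric",
  scanners = "character", scannerProb = "numeric",
  batchShift = "numeric", batchScale = "numeric",
  seed = "numeric"
))

setValidity("TwinSimConfig", function(object) {
  msg <- character()
  if (object@nMZ < 0 || object@nDZ < 0)
    msg <- c(msg, "nMZ and nDZ must be non-negative")
  cmp <- object@components
  need <- c("region", "metric", "model", "A", "C", "D", "E")
  if (!all(need %in% names(cmp))) {
    msg <- c(msg, sprintf("components must have columns %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(cmp)) {
    if (!all(cmp$model %in% VALID_MODELS))
      msg <- c(msg, "components$model must be ACE or ADE")
    tot <- cmp$A + cmp$C + cmp$D + cmp$E
    if (any(abs(tot - 1) > 0.01))
      msg <- c(msg, "per-region variance fractions must sum to 1 (within 0.01)")
    if (any(cmp[, c("A", "C", "D", "E")] < 0))
      msg <- c(msg, "variance fractions must be non-negative")
    if (any(cmp$E <= 0))
      msg <- c(msg, "E must be strictly positive (it absorbs measurement error)")
    if (any(cmp$model == "ACE" & cmp$D != 0) ||
        any(cmp$model == "ADE" & cmp$C != 0))
      msg <- c(msg, "C and D are confounded: D must be 0 under ACE, C under ADE")
    if (anyDuplicated(cmp[, c("region", "metric")]))
      msg <- c(msg, "duplicated (region, metric) rows in components")
  }
  if (length(object@ageRange) != 2 || any(object@ageRange <= 0))
    msg <- c(msg, "ageRange must be two positive ages")
  if (object@oppositeSexFraction < 0 || object@oppositeSexFraction > 1)
    msg <- c(msg, "oppositeSexFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Regional diffusion-metric container
#'
#' `RegionalMetrics` extends [SummarizedExperiment::SummarizedExperiment]:
#' assays are region-by-subject matrices, one per diffusion metric (any of
#' `FA`, `MD`, `AD`, `RD`), rows are atlas regions and columns are subjects.
#' Twin metadata (`pair_id`, `twin_index`, `zygosity`, `age`, `sex`,
#' `scanner`) lives in `colData`; operations that need it (adjustment,
#' correlation, harmonization) check for the columns they use.
#'
#' @export
setClass("RegionalMetrics", contains = "SummarizedExperiment")

setValidity("RegionalMetrics", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (is.null(an) || !length(an) || !all(an %in% VALID_METRICS))
    msg <- c(msg, sprintf("assay names must be among %s",
                          paste(VALID_METRICS, collapse = ", ")))
  if (is.null(rownames(object)))
    msg <- c(msg, "regions (rownames) must be named")
  if (is.null(colnames(object)))
    msg <- c(msg, "subjects (colnames) must be named")
  cd <- SummarizedExperiment::colData(object)
  if (all(c("pair_id", "twin_index") %in% names(cd))) {
    tab <- table(cd$pair_id)
    if (any(tab != 2))
      msg <- c(msg, "every pair_id must appear for exactly two subjects")
    if (!all(cd$twin_index %in% c(1L, 2L)))
      msg <- c(msg, "twin_index must be 1 or 2")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted ComBat harmonization model
#'
#' Parametric empirical-Bayes location/scale batch-harmonization model for one
#' feature matrix (features x subjects). Stores the covariate-adjusted grand
#' mean and pooled variance used for standardization, the per-batch EB-shrunk
#' location (`gammaStar`) and scale (`delta2Star`) estimates, and the
#' moment-matched normal / inverse-gamma prior hyperparameters, so that the
#' transform can be re-applied and audited. Created by [fitComBat()].
#'
#' @slot features Feature names (rows of the fitted matrix).
#' @slot batches Batch labels, in fitting order.
#' @slot covariates Names of preserved biological covariate columns.
#' @slot grandMean Per-feature covariate-free grand mean (batch-size weighted).
#' @slot covCoef Per-feature coefficients of the preserved covariates
#'   (features x covariate-design columns).
#' @slot varPooled Per-feature pooled residual variance.
#' @slot gammaStar,delta2Star Features x batches matrices of EB-shrunk batch
#'   location and squared-scale estimates (`delta2Star` strictly positive).
#' @slot priors List of per-batch hyperparameters (`gammaBar`, `tau2`,
#'   `aPrior`, `bPrior`).
#' @slot iterations Per-batch EB iteration counts at convergence.
#' @export
setClass("CombatModel", representation(
  features = "character", batches = "character", covariates = "character",
  grandMean = "numeric", covCoef = "matrix", varPooled = "numeric",
  gammaStar = "matrix", delta2Star = "matrix",
  priors = "list", iterations = "numeric"
))

setValidity("CombatModel", function(object) {
  msg <- character()
  if (any(object@delta2Star <= 0, na.rm = TRUE))
    msg <- c(msg, "delta2Star must be strictly positive")
  if (!identical(dim(object@gammaStar), dim(object@delta2Star)))
    msg <- c(msg, "gammaStar and delta2Star must have identical shape")
  if (length(object@batches) < 2)
    msg <- c(msg, "a ComBat model needs at least two batches")
  if (any(object@varPooled <= 0, na.rm = TRUE))
    msg <- c(msg, "pooled variances must be positive")
  if (length(msg)) msg else TRUE
})

#' Constrained biometric variance-component fit
#'
#' Result of [fitBiometricModel()]: standardized A/C/D/E variance fractions
#' for one region/metric under an ACE or ADE model, fitted by constrained
#' maximum likelihood to the MZ and DZ within-pair correlation matrices.
#'
#' @slot model `"ACE"` or `"ADE"`.
#' @slot components Named numeric `A`, `C`, `D`, `E` (non-negative, sum 1).
#' @slot G Heritability: A under ACE, A + D (broad sense) under ADE.
#' @slot observed Named numeric `r_mz`, `n_mz`, `r_dz`, `n_dz` input data.
#' @slot implied Model-implied `r_mz`, `r_dz` at the optimum.
#' @slot objective Minimized discrepancy (twice the negative profile
#'   log-likelihood up to a constant; 0 when the model reproduces the data).
#' @slot boundary Names of components pinned at their bound, if any.
#' @slot converged Logical optimizer status.
#' @export
setClass("BiometricFit", representation(
  model = "character", components = "numeric", G = "numeric",
  observed = "numeric", implied = "numeric",
  objective = "numeric", boundary = "character", converged = "logical"
))

setValidity("BiometricFit", function(object) {
  msg <- character()
  cc <- object@components
  if (!identical(names(cc), c("A", "C", "D", "E")))
    msg <- c(msg, "components must be named A, C, D, E")
  if (any(cc < -1e-8)) msg <- c(msg, "components must be non-negative")
  if (abs(sum(cc) - 1) > 1e-6) msg <- c(msg, "components must sum to 1")
  if (!object@model %in% VALID_MODELS) msg <- c(msg, "model must be ACE or ADE")
  if (object@model == "ACE" && cc[["D"]] != 0)
    msg <- c(msg, "D must be 0 under ACE")
  if (object@model == "ADE" && cc[["C"]] != 0)
    msg <- c(msg, "C must be 0 under ADE")
  if (object@G < -1e-8 || object@G > 1 + 1e-8)
    msg <- c(msg, "G must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
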