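#' Build a simulation configuration for a synthetic twin cohort
#'
#' Returns a validated [TwinSimConfig]. The defaults emulate the study
#' conditions of a population-based adolescent twin cohort: 33 MZ and 48 DZ
#' pairs (10 of the DZ pairs opposite-sex), ages drawn from a normal
#' distribution with mean 16.7 and SD 6.1 years truncated to 9--32, two
#' scanners sampled 47:34, and per-region/per-metric true variance components
#' taken from [referenceComponents()] (the published regional estimates for
#' that cohort). Scanner 2 applies a moderate batch effect (+0.3 residual-SD
#' location shift, 1.2x residual scale) so that harmonization has something
#' real to remove.
#'
#' @param nMZ,nDZ Pair counts.
#' @param components `data.frame(region, metric, model, A, C, D, E)` of true
#'   standardized variance fractions; defaults to [referenceComponents()].
#' @param ageRange,ageMean,ageSD Age distribution (years), truncated normal.
#' @param oppositeSexFraction Fraction of DZ pairs that are opposite-sex.
#' @param metricBase,metricSD Named per-metric trait mean and residual SD, in
#'   metric units (FA dimensionless; diffusivities in mm^2/s).
#' @param ageEffect,sexEffect Named per-metric linear age slope (units/year)
#'   and additive male offset.
#' @param scanners,scannerProb Batch labels and per-pair sampling weights.
#' @param batchShift,batchScale Named per-scanner additive shift (residual-SD
#'   units) and multiplicative residual scale.
#' @param seed Integer seed controlling all generator randomness.
#' @return A [TwinSimConfig] object.
#' @examples
#' cfg <- twinSimConfig(nMZ = 10, nDZ = 10, seed = 1)
#' cfg
#' @export
twinSimConfig <- function(nMZ = 33, nDZ = 48,
                          components = referenceComponents(),
                          ageRange = c(9, 32), ageMean = 16.7, ageSD = 6.1,
                          oppositeSexFraction = 10 / 48,
                          metricBase = c(FA = 0.5, MD = 0.80e-3,
                                         AD = 1.20e-3, RD = 0.60e-3),
                          metricSD = c(FA = 0.02, MD = 0.03e-3,
                                       AD = 0.04e-3, RD = 0.03e-3),
                          ageEffect = c(FA = 3e-3, MD = -6e-6,
                                        AD = -3e-6, RD = -7e-6),
                          sexEffect = c(FA = 5e-3, MD = -5e-6,
                                        AD = -5e-6, RD = -4e-6),
                          scanners = c("site1", "site2"),
                          scannerProb = c(47, 34) / 81,
                          batchShift = c(site1 = 0, site2 = 0.3),
                          batchScale = c(site1 = 1, site2 = 1.2),
                          seed = 20260318) {
  new("TwinSimConfig",
      nMZ = nMZ, nDZ = nDZ, components = components,
      ageRange = ageRange, ageMean = ageMean, ageSD = ageSD,
      oppositeSexFraction = oppositeSexFraction,
      metricBase = metricBase, metricSD = metricSD,
      ageEffect = ageEffect, sexEffect = sexEffect,
      scanners = scanners, scannerProb = scannerProb,
      batchShift = batchShift, batchScale = batchScale,
      seed = seed)
}

#' @describeIn twinSimConfig Single-region, single-metric configuration, handy
#'   for focused simulation experiments: one region named `region` with true
#'   components `(A, C, D, E)` under `model`, no covariate or batch effects
#'   unless requested.
#' @param A,C,D,E True standardized variance fractions (must sum to 1).
#' @param model `"ACE"` or `"ADE"`.
#' @param metric Which diffusion metric the region carries.
#' @param region Region name.
#' @param ... Passed on to `twinSimConfig()`.
#' @export
singleRegionConfig <- function(A, C = 0, D = 0, E = 1 - A - C - D,
                               model = if (D > 0) "ADE" else "ACE",
                               metric = "FA", region = "region1",
                               nMZ = 1000, nDZ = 1000, seed = 1, ...) {
  cmp <- data.frame(region = region, metric = metric, model = model,
                    A = A, C = C, D = D, E = E)
  twinSimConfig(nMZ = nMZ, nDZ = nDZ, components = cmp,
                ageEffect = c(FA = 0, MD = 0, AD = 0, RD = 0),
                sexEffect = c(FA = 0, MD = 0, AD = 0, RD = 0),
                batchShift = c(site1 = 0, site2 = 0),
                batchScale = c(site1 = 1, site2 = 1),
                seed = seed, ...)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a twin-pair roster with an exclusion cascade
#'
#' Draws `nMZ + nDZ` twin pairs (zygosity, member sexes, shared age, scanner)
#' and then marks pairs excluded, in the cascade order psychiatric history,
#' missing MRI, low-quality DTI. Exclusions are assigned to randomly chosen
#' still-eligible pairs, so retained + excluded always partition the initial
#' roster. MZ pairs are always same-sex; a configurable fraction of DZ pairs
#' is opposite-sex.
#'
#' @param config A [TwinSimConfig].
#' @param exclusions Named non-negative counts among `psychiatric`,
#'   `missing_mri`, `low_quality_dti`; their sum must not exceed the number of
#'   pairs.
#' @return `data.frame` with one row per pair: `pair_id`, `zygosity`,
#'   `sex_1`, `sex_2`, `age`, `scanner`, `excluded_reason` (`"none"` for
#'   retained pairs).
#' @examples
#' cfg <- twinSimConfig(seed = 7)
#' ros <- buildRoster(cfg, exclusions = c(psychiatric = 2))
#' table(ros$excluded_reason)
#' @seealso [retainedPairs()], [rosterSubjects()]
#' @export
buildRoster <- function(config,
                        exclusions = c(psychiatric = 0, missing_mri = 0,
                                       low_quality_dti = 0)) {
  stopifnot(is(config, "TwinSimConfig"))
  validObject(config)
  reasons <- c("psychiatric", "missing_mri", "low_quality_dti")
  if (!all(names(exclusions) %in% reasons))
    stop("unknown exclusion reason: ",
         paste(setdiff(names(exclusions), reasons), collapse = ", "))
  if (any(exclusions < 0)) stop("exclusion counts must be non-negative")
  n <- config@nMZ + config@nDZ
  if (sum(exclusions) > n) stop("exclusions exceed the initial pair count")

  set.seed(config@seed)
  zyg <- rep(c("MZ", "DZ"), c(config@nMZ, config@nDZ))
  age <- rtruncnorm1(n, config@ageMean, config@ageSD,
                     config@ageRange[1], config@ageRange[2])
  scanner <- config@scanners[
    sample.int(length(config@scanners), n, replace = TRUE,
               prob = config@scannerProb)]
  sex1 <- ifelse(runif(n) < 0.5, "M", "F")
  sex2 <- sex1
  dz <- which(zyg == "DZ")
  os <- dz[runif(length(dz)) < config@oppositeSexFraction]
  sex2[os] <- ifelse(sex1[os] == "M", "F", "M")

  roster <- data.frame(
    pair_id = sprintf("pair%03d", seq_len(n)),
    zygosity = zyg, sex_1 = sex1, sex_2 = sex2,
    age = age, scanner = scanner,
    excluded_reason = rep("none", n),
    stringsAsFactors = FALSE)

  for (r in reasons) {
    k <- if (r %in% names(exclusions)) exclusions[[r]] else 0
    if (is.na(k) || k == 0) next
    eligible <- which(roster$excluded_reason == "none")
    hit <- sample(eligible, k)
    roster$excluded_reason[hit] <- r
  }
  roster
}

#' Retained pairs of a roster
#'
#' @param roster Roster from [buildRoster()] (or read from CSV).
#' @return The subset of rows with `excluded_reason == "none"`.
#' @export
retainedPairs <- function(roster) {
  roster[roster$excluded_reason == "none", , drop = FALSE]
}

#' Expand a pair roster to one row per subject
#'
#' @param roster Roster of retained pairs (rows with a non-`"none"`
#'   `excluded_reason` are dropped first).
#' @return `data.frame` with columns `subject_id`, `pair_id`, `twin_index`,
#'   `zygosity`, `age`, `sex`, `scanner`, two rows per pair, twin 1 rows
#'   first within each pair ordering by pair.
#' @export
rosterSubjects <- function(roster) {
  roster <- retainedPairs(roster)
  long <- rbind(
    data.frame(pair_id = roster$pair_id, twin_index = 1L,
               zygosity = roster$zygosity, age = roster$age,
               sex = roster$sex_1, scanner = roster$scanner,
               stringsAsFactors = FALSE),
    data.frame(pair_id = roster$pair_id, twin_index = 2L,
               zygosity = roster$zygosity, age = roster$age,
               sex = roster$sex_2, scanner = roster$scanner,
               stringsAsFactors = FALSE))
  long <- long[order(long$pair_id, long$twin_index), , drop = FALSE]
  long <- cbind(subject_id = paste0(long$pair_id, "_", long$twin_index), long)
  rownames(long) <- long$subject_id
  long
}

#' Simulate regional diffusion metrics with known biometric structure
#'
#' For every (region, metric) in the configuration's component table, draws
#' latent standard-normal genetic and environmental factors scaled by
#' sqrt(A), sqrt(C), sqrt(D), sqrt(E). MZ co-twins share the additive and
#' dominance factors fully; DZ co-twins share them with correlation 1/2 and
#' 1/4 (the additive factor is built as sqrt(1/2) shared + sqrt(1/2) unique,
#' the dominance factor as sqrt(1/4) shared + sqrt(3/4) unique); the shared
#' environment C is common to both co-twins and E is independent. The implied
#' within-pair correlations are therefore A + C + D for MZ pairs and
#' A/2 + C + D/4 for DZ pairs. Linear age and additive sex effects are added
#' on the metric scale, and the scanner batch applies a location shift and a
#' residual scale (the structure ComBat models). FA values are clipped to
#' [0, 1].
#'
#' @param roster Pair roster; only retained pairs are simulated.
#' @param config A [TwinSimConfig].
#' @return A [RegionalMetrics] object with one assay per metric present in
#'   `config@components`.
#' @examples
#' cfg <- singleRegionConfig(A = 0.5, C = 0.2, nMZ = 50, nDZ = 50, seed = 3)
#' rm <- simulateTwinMetrics(buildRoster(cfg), cfg)
#' rm
#' @export
simulateTwinMetrics <- function(roster, config) {
  stopifnot(is(config, "TwinSimConfig"))
  validObject(config)
  cmp <- config@components
  if (!nrow(cmp)) stop("component table is empty: no regions to simulate")
  pairs <- retainedPairs(roster)
  subjects <- rosterSubjects(pairs)
  n <- nrow(pairs)
  mz <- pairs$zygosity == "MZ"

  set.seed(config@seed + 1L)
  metrics <- intersect(VALID_METRICS, unique(cmp$metric))
  assays <- list()
  for (m in metrics) {
    rows <- cmp[cmp$metric == m, , drop = FALSE]
    mat <- matrix(NA_real_, nrow(rows), 2L * n,
                  dimnames = list(rows$region, subjects$subject_id))
    for (i in seq_len(nrow(rows))) {
      A <- rows$A[i]; C <- rows$C[i]; D <- rows$D[i]; E <- rows$E[i]
      aSh <- rnorm(n); aU1 <- rnorm(n); aU2 <- rnorm(n)
      dSh <- rnorm(n); dU1 <- rnorm(n); dU2 <- rnorm(n)
      cSh <- rnorm(n); e1 <- rnorm(n); e2 <- rnorm(n)
      a1 <- ifelse(mz, aSh, sqrt(0.5) * aSh + sqrt(0.5) * aU1)
      a2 <- ifelse(mz, aSh, sqrt(0.5) * aSh + sqrt(0.5) * aU2)
      d1 <- ifelse(mz, dSh, sqrt(0.25) * dSh + sqrt(0.75) * dU1)
      d2 <- ifelse(mz, dSh, sqrt(0.25) * dSh + sqrt(0.75) * dU2)
      z1 <- sqrt(A) * a1 + sqrt(C) * cSh + sqrt(D) * d1 + sqrt(E) * e1
      z2 <- sqrt(A) * a2 + sqrt(C) * cSh + sqrt(D) * d2 + sqrt(E) * e2
      shift <- config@batchShift[pairs$scanner]
      scale <- config@batchScale[pairs$scanner]
      base <- config@metricBase[[m]] +
        config@ageEffect[[m]] * (pairs$age - config@ageMean)
      sexEff <- config@sexEffect[[m]]
      v1 <- base + sexEff * (pairs$sex_1 == "M") +
        config@metricSD[[m]] * (shift + scale * z1)
      v2 <- base + sexEff * (pairs$sex_2 == "M") +
        config@metricSD[[m]] * (shift + scale * z2)
      if (m == "FA") { v1 <- pmin(pmax(v1, 0), 1); v2 <- pmin(pmax(v2, 0), 1) }
      vals <- rbind(v1, v2)  # twin_index 1 then 2 per pair
      colnames(vals) <- NULL
      mat[i, paste0(pairs$pair_id, "_1")] <- vals[1, ]
      mat[i, paste0(pairs$pair_id, "_2")] <- vals[2, ]
    }
    assays[[m]] <- mat
  }
  RegionalMetrics(assays, subjects)
}

#' Simulate labeled skeleton volumes around known regional values
#'
#' Builds a 3D integer label volume plus 4D per-metric skeleton maps whose
#' labeled voxels scatter (with optional Gaussian voxel noise) around supplied
#' per-subject regional values; all voxels outside every label are exactly
#' zero, mimicking a TBSS skeleton projection. Used to exercise the regional
#' extraction stage without real imaging data.
#'
#' @param atlasSpec Either a named integer vector (region -> voxel count;
#'   voxel positions are assigned disjointly) or a named list of integer
#'   linear voxel indices per region (overlapping indices are an error).
#' @param values Region x subject numeric matrix of target regional values
#'   (rownames must cover `names(atlasSpec)`), or a [RegionalMetrics] from
#'   which one matrix per assay is taken.
#' @param voxelNoiseSD Gaussian SD added independently per voxel (>= 0).
#' @param seed Integer seed.
#' @param dim Optional 3D array dimensions; defaults to a cube with roughly
#'   half its voxels background.
#' @return A list with `labels` (3D integer array), `labelNames` (named
#'   character, label id -> region), and `maps` (named list of 4D arrays,
#'   one per metric).
#' @export
simulateSkeletonVolumes <- function(atlasSpec, values, voxelNoiseSD = 0,
                                    seed = 1, dim = NULL) {
  if (voxelNoiseSD < 0) stop("voxelNoiseSD must be non-negative")
  if (is(values, "RegionalMetrics")) {
    mats <- as.list(SummarizedExperiment::assays(values))
    mats <- lapply(mats, as.matrix)
  } else {
    mats <- list(FA = as.matrix(values))
  }
  regions <- names(atlasSpec)
  if (is.null(regions)) stop("atlasSpec must be named by region")
  if (!all(regions %in% rownames(mats[[1]])))
    stop("atlasSpec regions missing from the value matrix: ",
         paste(setdiff(regions, rownames(mats[[1]])), collapse = ", "))

  if (is.list(atlasSpec)) {
    idx <- lapply(atlasSpec, as.integer)
    all_idx <- unlist(idx, use.names = FALSE)
    if (anyDuplicated(all_idx))
      stop("overlapping region labels: a voxel may carry at most one label")
    if (any(all_idx < 1)) stop("voxel indices must be positive")
    total <- max(all_idx)
  } else {
    counts <- as.integer(atlasSpec)
    if (any(counts < 1)) stop("every region needs at least one voxel")
    ends <- cumsum(counts)
    idx <- mapply(function(a, b) seq.int(a, b), c(1L, head(ends, -1) + 1L),
                  ends, SIMPLIFY = FALSE)
    names(idx) <- regions
    total <- ends[length(ends)]
  }
  if (is.null(dim)) {
    side <- max(2L, ceiling((2 * total)^(1 / 3)))
    dim <- rep(side, 3L)
  }
  if (prod(dim) < total) stop("volume dimensions too small for the atlas")

  labels <- array(0L, dim)
  labelNames <- setNames(regions, seq_along(regions))
  for (i in seq_along(regions)) labels[idx[[i]]] <- i

  nsubj <- ncol(mats[[1]])
  set.seed(seed)
  maps <- lapply(mats, function(mat) {
    vol <- array(0, c(dim, nsubj))
    nvox <- prod(dim)
    for (s in seq_len(nsubj)) {
      off <- (s - 1L) * nvox
      for (i in seq_along(regions)) {
        v <- mat[regions[i], s]
        vox <- rep(v, length(idx[[i]]))
        if (voxelNoiseSD > 0) vox <- vox + rnorm(length(vox), 0, voxelNoiseSD)
        vol[off + idx[[i]]] <- vox
      }
    }
    vol
  })
  list(labels = labels, labelNames = labelNames, maps = maps)
}

#' Write simulated skeleton volumes as NIfTI-1 files
#'
#' @param sim Result of [simulateSkeletonVolumes()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written (`labels.nii.gz`
#'   plus `<metric>.nii.gz` per map).
#' @export
writeSkeletonNifti <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labels = file.path(dir, "labels.nii.gz"))
  RNifti::writeNifti(sim$labels, paths[["labels"]])
  for (m in names(sim$maps)) {
    p <- file.path(dir, paste0(m, ".nii.gz"))
    RNifti::writeNifti(sim$maps[[m]], p)
    paths[[m]] <- p
  }
  invisible(paths)
}
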