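#' Diffusion tensor scalar maps from eigenvalue maps
#'
#' Computes the four standard tensor scalar metrics voxelwise from the three
#' sorted eigenvalue maps (L1 >= L2 >= L3, mm^2/s): axial diffusivity
#' AD = L1; mean diffusivity MD = (L1 + L2 + L3)/3; radial diffusivity
#' RD = (L2 + L3)/2; and fractional anisotropy
#' FA = sqrt(3/2) * sqrt(sum_i (L_i - MD)^2) / sqrt(sum_i L_i^2),
#' with FA defined as 0 at all-zero voxels. Slightly negative eigenvalues
#' (numerical noise from tensor fitting) are clamped to zero with a warning;
#' negative values beyond `tol` in magnitude are an error.
#'
#' @param L1,L2,L3 Numeric arrays (any congruent shape) of tensor
#'   eigenvalues, largest first.
#' @param tol Magnitude beyond which a negative eigenvalue is treated as a
#'   data error rather than numerical noise.
#' @return Named list of arrays `FA`, `MD`, `AD`, `RD`, same shape as input.
#' @examples
#' m <- tensorMetrics(1.5e-3, 1.0e-3, 0.5e-3)
#' m$RD  # 0.75e-3
#' @export
tensorMetrics <- function(L1, L2, L3, tol = 1e-6) {
  if (!all(dim(L1) %||% length(L1) == dim(L2) %||% length(L2)) ||
      !all(dim(L1) %||% length(L1) == dim(L3) %||% length(L3)))
    stop("eigenvalue maps must share shape")
  neg <- pmin(L1, L2, L3, na.rm = FALSE)
  if (any(neg < -tol, na.rm = TRUE))
    stop("negative eigenvalues beyond tolerance")
  if (any(neg < 0, na.rm = TRUE)) {
    warning("clamping slightly negative eigenvalues to 0")
    L1 <- pmax(L1, 0); L2 <- pmax(L2, 0); L3 <- pmax(L3, 0)
  }
  if (any(L1 - L2 < -tol | L2 - L3 < -tol, na.rm = TRUE))
    stop("eigenvalue ordering L1 >= L2 >= L3 violated")
  MD <- (L1 + L2 + L3) / 3
  num <- (L1 - MD)^2 + (L2 - MD)^2 + (L3 - MD)^2
  den <- L1^2 + L2^2 + L3^2
  FA <- sqrt(1.5) * sqrt(num) / sqrt(ifelse(den > 0, den, 1))
  FA[den == 0] <- 0
  FA <- pmin(FA, 1)
  list(FA = FA, MD = MD, AD = L1, RD = (L2 + L3) / 2)
}

#' Read skeletonised 4D metric maps and a 3D label atlas from NIfTI
#'
#' @param mapPaths Named character vector of NIfTI paths, one 4D skeleton map
#'   per metric (names among `FA`, `MD`, `AD`, `RD`).
#' @param atlasPath Path to the 3D integer label volume.
#' @return List with `maps` (named list of 4D arrays) and `labels` (3D
#'   integer array), ready for [extractRegionalMeans()].
#' @export
readSkeletonMaps <- function(mapPaths, atlasPath) {
  if (is.null(names(mapPaths)) || !all(names(mapPaths) %in% VALID_METRICS))
    stop("mapPaths must be named by metric (FA, MD, AD, RD)")
  maps <- lapply(mapPaths, function(p) {
    a <- RNifti::readNifti(p)
    array(as.numeric(a), dim(a))
  })
  labels <- RNifti::readNifti(atlasPath)
  labels <- array(as.integer(round(as.numeric(labels))), dim(labels))
  list(maps = maps, labels = labels)
}

#' Extract per-region mean metrics from skeletonised 4D maps
#'
#' For every subject, atlas region and metric, averages the map over the
#' voxels carrying that region's label, excluding voxels whose value is
#' exactly zero (zeros mark positions outside the skeleton projection, so
#' they carry no tissue signal). A region with no qualifying voxel for a
#' subject yields `NA` and is reported in the returned object's metadata
#' under `missing_cells`. Regions named in `exclude` are dropped from the
#' output entirely.
#'
#' @param maps Named list of 4D arrays (x, y, z, subject), one per metric;
#'   all must share spatial shape with `labels` and subject count.
#' @param labels 3D integer label volume; 0 is background. Every non-zero
#'   label must be named in `labelNames`.
#' @param labelNames Named character: label id -> region name. Defaults to
#'   the JHU ICBM-DTI-81 table ([jhuRegionLabels()]).
#' @param exclude Region names to drop; defaults to
#'   [defaultRegionExclusions()] restricted to regions actually present.
#' @param subjects Optional subject identifiers for the fourth dimension;
#'   defaults to `subj1, subj2, ...`.
#' @return A [RegionalMetrics] with one assay per supplied metric.
#' @export
extractRegionalMeans <- function(maps, labels,
                                 labelNames = jhuRegionLabels(),
                                 exclude = defaultRegionExclusions(),
                                 subjects = NULL) {
  if (is.null(names(maps)) || !all(names(maps) %in% VALID_METRICS))
    stop("maps must be named by metric (FA, MD, AD, RD)")
  sdim <- dim(labels)
  nsubj <- dim(maps[[1]])[4]
  for (m in names(maps)) {
    dm <- dim(maps[[m]])
    if (length(dm) != 4 || !identical(dm[1:3], sdim) || dm[4] != nsubj)
      stop("shape mismatch between atlas and 4D map for metric ", m)
  }
  present <- sort(setdiff(unique(as.integer(labels)), 0L))
  unknown <- setdiff(as.character(present), names(labelNames))
  if (length(unknown))
    stop("unknown atlas label(s) without a region name: ",
         paste(unknown, collapse = ", "))
  regions <- unname(labelNames[as.character(present)])
  keep <- !(regions %in% exclude)
  if (!any(keep)) stop("all regions excluded: nothing to extract")
  present <- present[keep]; regions <- regions[keep]
  if (is.null(subjects)) subjects <- sprintf("subj%d", seq_len(nsubj))

  nvox <- prod(sdim)
  idxByRegion <- lapply(present, function(lab) which(labels == lab))
  assays <- lapply(maps, function(vol) {
    flat <- matrix(vol, nvox, nsubj)
    out <- matrix(NA_real_, length(present), nsubj,
                  dimnames = list(regions, subjects))
    for (i in seq_along(present)) {
      sub <- flat[idxByRegion[[i]], , drop = FALSE]
      sub[sub == 0] <- NA_real_
      mu <- colMeans(sub, na.rm = TRUE)
      mu[is.nan(mu)] <- NA_real_
      out[i, ] <- mu
    }
    out
  })
  x <- RegionalMetrics(assays)
  miss <- do.call(rbind, lapply(names(assays), function(m) {
    w <- which(is.na(assays[[m]]), arr.ind = TRUE)
    if (!nrow(w)) return(NULL)
    data.frame(metric = m, region = regions[w[, 1]],
               subject = subjects[w[, 2]], stringsAsFactors = FALSE)
  }))
  S4Vectors::metadata(x)$missing_cells <- miss
  if (!is.null(miss) && nrow(miss))
    twin_log("extraction: %d region/subject cells had no skeleton voxels",
             nrow(miss))
  x
}

#' Drop excluded regions from a regional metric table
#'
#' @param x A [RegionalMetrics] object.
#' @param exclude Region names to drop. Names not present in the table are
#'   skipped with a warning.
#' @return `x` without the excluded regions.
#' @export
applyRegionExclusions <- function(x, exclude = defaultRegionExclusions()) {
  absent <- setdiff(exclude, regionNames(x))
  if (length(absent))
    warning("exclusion name(s) not in table, skipped: ",
            paste(absent, collapse = ", "))
  keep <- !(regionNames(x) %in% exclude)
  x[keep, ]
}
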