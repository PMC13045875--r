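test_that("tensor scalar metrics match their closed forms", {
  iso <- tensorMetrics(1e-3, 1e-3, 1e-3)
  expect_equal(iso$FA, 0)
  expect_equal(iso$MD, 1e-3)
  expect_equal(iso$AD, 1e-3)
  expect_equal(iso$RD, 1e-3)

  m <- tensorMetrics(1.5e-3, 1.0e-3, 0.5e-3)
  expect_equal(m$RD, 0.75e-3)
  expect_equal(m$MD, 1.0e-3)
  expect_equal(m$AD, 1.5e-3)

  expect_equal(tensorMetrics(1, 0, 0)$FA, 1)
  expect_equal(tensorMetrics(0, 0, 0)$FA, 0)  # all-zero convention
})

test_that("FA bounds and MD identity hold on random eigenvalue fields", {
  set.seed(4)
  for (i in 1:5) {
    L <- array(runif(3 * 64, 0, 2e-3), c(4, 4, 4, 3))
    Ls <- apply(L, c(1, 2, 3), sort, decreasing = TRUE)
    m <- tensorMetrics(Ls[1, , , ], Ls[2, , , ], Ls[3, , , ])
    expect_true(all(m$FA >= 0 & m$FA <= 1))
    expect_equal(m$MD, (m$AD + 2 * m$RD) / 3, tolerance = 1e-12)
  }
})

test_that("slightly negative eigenvalues clamp; larger ones error", {
  expect_warning(m <- tensorMetrics(1e-3, 1e-3, -1e-9), "clamping")
  expect_equal(m$RD, 0.5e-3)
  expect_error(tensorMetrics(1e-3, 1e-3, -1e-3), "beyond tolerance")
})

test_that("regional extraction equals the brute-force voxel loop", {
  for (seed in c(31, 32, 33)) {
    sim <- random_skeleton_fixture(seed)
    rm <- extractRegionalMeans(sim$maps, sim$labels, sim$labelNames,
                               exclude = character())
    oracle <- brute_force_means(sim$maps$FA, sim$labels, sim$labelNames)
    got <- SummarizedExperiment::assay(rm, "FA")
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  }
})

test_that("zero voxels are excluded and empty regions flagged missing", {
  vals <- matrix(c(0.4, 0.7), 1, 2, dimnames = list("r1", c("s1", "s2")))
  sim <- simulateSkeletonVolumes(c(r1 = 3), vals, seed = 1)
  idx <- which(sim$labels == 1)
  nvox <- prod(dim(sim$labels))
  # subject 1: voxels {0.4, 0.6, 0.0} -> mean 0.5
  sim$maps$FA[idx[1]] <- 0.4
  sim$maps$FA[idx[2]] <- 0.6
  sim$maps$FA[idx[3]] <- 0
  # subject 2: all voxels zero -> missing cell
  sim$maps$FA[nvox + idx] <- 0
  rm <- extractRegionalMeans(sim$maps, sim$labels, sim$labelNames,
                             exclude = character(),
                             subjects = c("s1", "s2"))
  a <- SummarizedExperiment::assay(rm, "FA")
  expect_equal(a["r1", "s1"], 0.5)
  expect_true(is.na(a["r1", "s2"]))
  miss <- S4Vectors::metadata(rm)$missing_cells
  expect_equal(miss$subject, "s2")
})

test_that("a 48-label atlas with the standard exclusions yields 42 regions", {
  labs <- jhuRegionLabels()
  vals <- matrix(runif(48 * 2, 0.2, 0.8), 48, 2,
                 dimnames = list(unname(labs), c("s1", "s2")))
  sim <- simulateSkeletonVolumes(setNames(rep(2L, 48), unname(labs)), vals,
                                 seed = 5)
  rm <- extractRegionalMeans(sim$maps, sim$labels, labelNames = sim$labelNames,
                             exclude = defaultRegionExclusions())
  expect_equal(nrow(rm), 42)
  expect_false(any(defaultRegionExclusions() %in% regionNames(rm)))
})

test_that("table-level region exclusion drops exactly the named regions", {
  co <- sim_cohort(A = 0.5, nPairs = 10, seed = 6)
  x <- co$data
  expect_identical(regionNames(applyRegionExclusions(x, character())),
                   regionNames(x))
  cfg48 <- twinSimConfig(
    nMZ = 5, nDZ = 5, seed = 6,
    components = data.frame(region = unname(jhuRegionLabels()),
                            metric = "FA", model = "ACE",
                            A = 0.5, C = 0.2, D = 0, E = 0.3))
  x48 <- simulateTwinMetrics(buildRoster(cfg48), cfg48)
  x42 <- applyRegionExclusions(x48, defaultRegionExclusions())
  expect_equal(nrow(x42), 42)
  expect_warning(out <- applyRegionExclusions(x42, "not_a_region"),
                 "not in table")
  expect_identical(regionNames(out), regionNames(x42))
})

test_that("extraction rejects malformed inputs", {
  sim <- random_skeleton_fixture(40)
  badmap <- list(FA = sim$maps$FA[, , -1, , drop = FALSE])
  expect_error(extractRegionalMeans(badmap, sim$labels, sim$labelNames),
               "shape mismatch")
  labs <- sim$labels
  labs[which(labs == 0)[1]] <- 99L
  expect_error(extractRegionalMeans(sim$maps, labs, sim$labelNames),
               "unknown atlas label")
})

test_that("subject order permutation permutes columns but not values", {
  sim <- random_skeleton_fixture(50, nSubj = 5)
  rm1 <- extractRegionalMeans(sim$maps, sim$labels, sim$labelNames,
                              exclude = character())
  perm <- c(3, 1, 5, 2, 4)
  permMaps <- lapply(sim$maps, function(v) v[, , , perm, drop = FALSE])
  rm2 <- extractRegionalMeans(permMaps, sim$labels, sim$labelNames,
                              exclude = character())
  a1 <- SummarizedExperiment::assay(rm1, "FA")
  a2 <- SummarizedExperiment::assay(rm2, "FA")
  expect_equal(unname(a2), unname(a1[, perm]))
})

test_that("NIfTI round trip preserves maps, labels and extraction output", {
  sim <- random_skeleton_fixture(60, nSubj = 3)
  dir <- tempfile("vols")
  paths <- writeSkeletonNifti(sim, dir)
  back <- readSkeletonMaps(paths["FA"], paths[["labels"]])
  expect_equal(back$maps$FA, sim$maps$FA, tolerance = 1e-12)
  expect_identical(back$labels, sim$labels)
  rm <- extractRegionalMeans(back$maps, back$labels, sim$labelNames,
                             exclude = character())
  oracle <- brute_force_means(sim$maps$FA, sim$labels, sim$labelNames)
  expect_equal(unname(SummarizedExperiment::assay(rm, "FA")),
               unname(oracle), tolerance = 1e-12)
})
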