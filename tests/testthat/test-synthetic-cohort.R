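test_that("roster generation respects counts, zygosity and sex invariants", {
  cfg <- twinSimConfig(nMZ = 33, nDZ = 48, seed = 2)
  ros <- buildRoster(cfg)
  expect_equal(nrow(ros), 81)
  expect_equal(sum(ros$zygosity == "MZ"), 33)
  expect_equal(sum(ros$zygosity == "DZ"), 48)
  mz <- ros[ros$zygosity == "MZ", ]
  expect_true(all(mz$sex_1 == mz$sex_2))
  expect_true(all(ros$age > 0))
  expect_true(all(ros$age >= 9 & ros$age <= 32))

  empty <- buildRoster(twinSimConfig(nMZ = 0, nDZ = 0, seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("exclusion cascade partitions the roster and retains the rest", {
  cfg <- twinSimConfig(nMZ = 50, nDZ = 71, seed = 3)  # 121 initial pairs
  exc <- c(psychiatric = 6, missing_mri = 19, low_quality_dti = 15)
  ros <- buildRoster(cfg, exclusions = exc)
  expect_equal(nrow(ros), 121)
  expect_equal(as.vector(table(ros$excluded_reason)[names(exc)]),
               unname(exc))
  kept <- retainedPairs(ros)
  expect_equal(nrow(kept), 81)
  expect_equal(nrow(rosterSubjects(kept)), 162)
  # partition: retained + excluded = initial
  expect_equal(nrow(kept) + sum(ros$excluded_reason != "none"), nrow(ros))

  expect_error(buildRoster(cfg, exclusions = c(psychiatric = -1)),
               "non-negative")
  expect_error(buildRoster(cfg, exclusions = c(psychiatric = 200)),
               "exceed")
})

test_that("generator reproduces the biometric covariance algebra", {
  # ACE truth from a published splenium FA row: rMZ = 0.89, rDZ = 0.54
  tc <- sim_correlations(A = 0.70, C = 0.19, nPairs = 10000, seed = 11)
  expect_equal(tc$r[tc$zygosity == "MZ"], 0.89, tolerance = 0.02 / 0.89)
  expect_equal(tc$r[tc$zygosity == "DZ"], 0.54, tolerance = 0.02 / 0.54)

  # ADE: rMZ = A + D, rDZ = A/2 + D/4
  tc <- sim_correlations(A = 0.40, D = 0.30, nPairs = 10000, seed = 12)
  expect_equal(tc$r[tc$zygosity == "MZ"], 0.70, tolerance = 0.03 / 0.70)
  expect_equal(tc$r[tc$zygosity == "DZ"], 0.275, tolerance = 0.03 / 0.275)

  # pure noise: both correlations near zero
  tc <- sim_correlations(A = 0, C = 0, nPairs = 5000, seed = 13)
  expect_true(all(abs(tc$r) < 0.05))
})

test_that("identical config and seed give bit-identical outputs", {
  run <- function() {
    cfg <- twinSimConfig(nMZ = 20, nDZ = 20, seed = 7)
    ros <- buildRoster(cfg, exclusions = c(missing_mri = 3))
    rm <- simulateTwinMetrics(ros, cfg)
    f <- tempfile(fileext = ".csv")
    writeRegionalTable(rm, f)
    list(roster = ros, bytes = readBin(f, "raw", file.size(f)))
  }
  a <- run(); b <- run()
  expect_identical(a$roster, b$roster)
  expect_identical(a$bytes, b$bytes)
})

test_that("covariate and batch effects enter the simulated values", {
  cfg <- twinSimConfig(nMZ = 300, nDZ = 300, seed = 21)
  ros <- buildRoster(cfg)
  rm <- simulateTwinMetrics(ros, cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(rm))
  fa <- SummarizedExperiment::assay(rm, "FA")
  slope <- coef(lm(fa["sCC", ] ~ cd$age + factor(cd$sex)))[2]
  expect_equal(unname(slope), 3e-3, tolerance = 0.3)
  # scanner 2 shifts the FA location by +0.3 residual SDs = 0.006
  res <- residuals(lm(fa["CST_R", ] ~ cd$age + factor(cd$sex)))
  diff <- mean(res[cd$scanner == "site2"]) - mean(res[cd$scanner == "site1"])
  expect_gt(diff, 0.002)
  expect_true(all(fa >= 0 & fa <= 1))
})

test_that("skeleton volume fixtures honour labels, zeros and noise", {
  vals <- matrix(0.5, 1, 3, dimnames = list("r1", paste0("s", 1:3)))
  sim <- simulateSkeletonVolumes(c(r1 = 6), vals, voxelNoiseSD = 0, seed = 1)
  lab <- sim$labels
  expect_true(all(sim$maps$FA[which(lab == 1)] == 0.5))
  expect_true(all(sim$maps$FA[rep(which(lab == 0), 3)] == 0))

  two <- simulateSkeletonVolumes(c(a = 3, b = 4),
                                 matrix(c(1, 2), 2, 1,
                                        dimnames = list(c("a", "b"), "s1")),
                                 seed = 1)
  expect_equal(sort(setdiff(unique(as.vector(two$labels)), 0L)), c(1L, 2L))

  expect_error(
    simulateSkeletonVolumes(list(a = 1:3, b = 3:5),
                            matrix(c(1, 2), 2, 1,
                                   dimnames = list(c("a", "b"), "s1"))),
    "overlapping")
  expect_error(simulateSkeletonVolumes(c(r1 = 6), vals, voxelNoiseSD = -1),
               "non-negative")
})

test_that("invalid simulation configurations are rejected", {
  expect_error(twinSimConfig(nMZ = -1), "non-negative")
  bad <- data.frame(region = "r", metric = "FA", model = "ACE",
                    A = 0.6, C = 0.5, D = 0, E = 0.1)
  expect_error(twinSimConfig(components = bad), "sum to 1")
  bad2 <- data.frame(region = "r", metric = "FA", model = "ADE",
                     A = 0.5, C = 0.2, D = 0, E = 0.3)
  expect_error(twinSimConfig(components = bad2), "confounded")
  expect_error(
    simulateTwinMetrics(buildRoster(twinSimConfig(seed = 1)),
                        twinSimConfig(components = data.frame(
                          region = character(), metric = character(),
                          model = character(), A = numeric(), C = numeric(),
                          D = numeric(), E = numeric()))),
    "empty")
})
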