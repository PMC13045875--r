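test_that("age/sex residualization satisfies least-squares properties", {
  co <- sim_cohort(A = 0.5, C = 0.2, nPairs = 100, seed = 41)
  cfg <- twinSimConfig(nMZ = 100, nDZ = 100, seed = 41)
  rm <- simulateTwinMetrics(buildRoster(cfg), cfg)
  res <- adjustAgeSex(rm)
  cd <- as.data.frame(SummarizedExperiment::colData(res))
  for (m in c("FA", "MD")) {
    a <- SummarizedExperiment::assay(res, m)
    expect_true(all(abs(rowMeans(a)) < 1e-12))
    corAge <- apply(a, 1, function(y) abs(cor(y, cd$age)))
    expect_true(all(corAge < 1e-10))
  }
  # with no covariate effects, residuals equal centered values
  rm0 <- co$data
  res0 <- adjustAgeSex(rm0)
  a0 <- SummarizedExperiment::assay(rm0, "FA")
  r0 <- SummarizedExperiment::assay(res0, "FA")
  fit <- lm(a0[1, ] ~ as.data.frame(SummarizedExperiment::colData(rm0))$age +
              factor(SummarizedExperiment::colData(rm0)$sex))
  expect_equal(unname(r0[1, ]), unname(residuals(fit)), tolerance = 1e-10)

  bad <- rm0
  SummarizedExperiment::colData(bad)$age[3] <- NA
  expect_error(adjustAgeSex(bad), "missing age/sex covariate")
})

test_that("double-entry correlation is labeling-invariant and equals the ICC", {
  co <- sim_cohort(A = 0.6, C = 0.1, nPairs = 60, seed = 42)
  tc1 <- twinCorrelations(co$data)

  # swap twin order within a random subset of pairs: estimates unchanged
  x <- co$data
  cd <- SummarizedExperiment::colData(x)
  set.seed(99)
  flip <- sample(unique(cd$pair_id), 20)
  idx <- cd$pair_id %in% flip
  cd$twin_index[idx] <- 3L - cd$twin_index[idx]
  SummarizedExperiment::colData(x) <- cd
  tc2 <- twinCorrelations(x)
  expect_equal(tc1$r, tc2$r, tolerance = 1e-12)

  # oracle: ANOVA intraclass correlation from the stacked 2n rows
  a <- SummarizedExperiment::assay(co$data, "FA")
  for (z in c("MZ", "DZ")) {
    sel <- cd$zygosity == z
    v1 <- a[1, sel & cd$twin_index == 1]
    v2 <- a[1, sel & cd$twin_index == 2]
    xx <- c(v1, v2); yy <- c(v2, v1)
    mu <- mean(xx)
    icc <- sum((xx - mu) * (yy - mu)) / sum((xx - mu)^2)
    expect_equal(tc1$r[tc1$zygosity == z], icc, tolerance = 1e-12)
  }
})

test_that("perfect within-pair agreement gives r = 1; missing pairs drop", {
  cfg <- singleRegionConfig(A = 0.5, nMZ = 10, nDZ = 10, seed = 43)
  rm <- simulateTwinMetrics(buildRoster(cfg), cfg)
  a <- SummarizedExperiment::assay(rm, "FA")
  cd <- SummarizedExperiment::colData(rm)
  t1 <- cd$twin_index == 1
  # copy twin 1 onto twin 2
  ord <- match(paste0(cd$pair_id[t1], "_2"), colnames(a))
  a[, ord] <- a[, which(t1)]
  SummarizedExperiment::assay(rm, "FA") <- a
  tc <- twinCorrelations(rm)
  expect_equal(tc$r, c(1, 1), tolerance = 1e-12)

  # NA in one member drops that pair only for that cell
  a[1, ord[1]] <- NA
  SummarizedExperiment::assay(rm, "FA") <- a
  tc2 <- twinCorrelations(rm)
  expect_equal(tc2$n_pairs[tc2$zygosity == "MZ"], 9L)

  # fewer than 3 complete pairs -> missing estimate
  a[1, ord[1:8]] <- NA
  SummarizedExperiment::assay(rm, "FA") <- a
  tc3 <- twinCorrelations(rm)
  expect_true(is.na(tc3$r[tc3$zygosity == "MZ"]))
})

test_that("adjustment+correlation is invariant to constant regional shifts", {
  co <- sim_cohort(A = 0.5, C = 0.2, nPairs = 50, seed = 44)
  tc1 <- twinCorrelations(adjustAgeSex(co$data))
  shifted <- co$data
  SummarizedExperiment::assay(shifted, "FA") <-
    SummarizedExperiment::assay(shifted, "FA") + 5
  tc2 <- twinCorrelations(adjustAgeSex(shifted))
  expect_equal(tc1$r, tc2$r, tolerance = 1e-9)
})

test_that("Fisher-z comparison matches the closed form and is monotone", {
  # equal correlations: no evidence either way
  eq <- compareTwinCorrelations(0.5, 30, 0.5, 40)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 0.5)

  # genu-of-corpus-callosum FA row: z ~ 3.13, one-sided p ~ 9e-4
  cmp <- compareTwinCorrelations(0.81, 33, 0.37, 48)
  z_oracle <- (atanh(0.81) - atanh(0.37)) / sqrt(1 / 30 + 1 / 45)
  expect_equal(cmp$z, z_oracle, tolerance = 1e-12)
  expect_equal(cmp$z, 3.13, tolerance = 0.01)
  expect_equal(cmp$p, 9e-4, tolerance = 0.05)
  expect_identical(cmp$direction, "MZ>DZ")

  # p strictly decreases as r_mz grows
  ps <- vapply(seq(0.4, 0.9, by = 0.1), function(r)
    compareTwinCorrelations(r, 33, 0.37, 48)$p, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(compareTwinCorrelations(1, 33, 0.3, 48), "infinite")
  expect_error(compareTwinCorrelations(0.5, 3, 0.3, 48), "at least 4")
})

test_that("metric summaries reduce correctly", {
  expect_equal(summarizeMetricCorrelations(0.42),
               c(mean = 0.42, min = 0.42, max = 0.42))
  s <- summarizeMetricCorrelations(c(0.1, 0.2, NA, 0.6))
  expect_equal(unname(s), c(0.30, 0.10, 0.60))
  expect_error(summarizeMetricCorrelations(NA_real_), "no correlation")
})

test_that("demographic tests match their textbook formulas", {
  cfg <- twinSimConfig(nMZ = 30, nDZ = 40, seed = 45)
  ros <- buildRoster(cfg)
  # identical ages across groups -> t = 0, p = 1
  ros2 <- ros
  ros2$age <- rep(15, nrow(ros2))
  dt <- demographicsTests(ros2)
  expect_equal(dt$age$statistic, 0)
  expect_equal(dt$age$p, 1)

  # chi-square equals sum (O - E)^2 / E on the observed table
  dt2 <- demographicsTests(ros)
  tab <- dt2$sex$table
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(dt2$sex$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_true(dt2$sex$p >= 0 && dt2$sex$p <= 1)

  # proportional sex composition -> chi-square 0
  ros3 <- data.frame(
    pair_id = sprintf("p%02d", 1:20),
    zygosity = rep(c("MZ", "DZ"), each = 10),
    sex_1 = rep(c("M", "F"), 10), sex_2 = rep(c("M", "F"), 10),
    age = rnorm(20, 15, 2), scanner = "site1",
    excluded_reason = "none", stringsAsFactors = FALSE)
  dt3 <- demographicsTests(ros3)
  expect_equal(dt3$sex$statistic, 0, tolerance = 1e-12)

  expect_error(demographicsTests(ros3[ros3$zygosity == "MZ", ]),
               "non-empty")
})
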