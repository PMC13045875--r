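# shared fixture builders: everything is generated in code at test time

# single-region cohort with chosen truth, no covariate/batch effects
sim_cohort <- function(A, C = 0, D = 0, nPairs = 1000, seed = 1,
                       metric = "FA") {
  cfg <- singleRegionConfig(A = A, C = C, D = D, metric = metric,
                            nMZ = nPairs, nDZ = nPairs, seed = seed)
  ros <- buildRoster(cfg)
  list(config = cfg, roster = ros,
       data = simulateTwinMetrics(ros, cfg))
}

# double-entry correlations straight from a simulated cohort
sim_correlations <- function(...) {
  co <- sim_cohort(...)
  twinCorrelations(adjustAgeSex(co$data))
}

# brute-force regional means: triple loop over voxels, zeros excluded
brute_force_means <- function(map4d, labels, labelNames) {
  dims <- dim(map4d)
  nsubj <- dims[4]
  labs <- sort(setdiff(unique(as.integer(labels)), 0L))
  out <- matrix(NA_real_, length(labs), nsubj,
                dimnames = list(unname(labelNames[as.character(labs)]), NULL))
  for (li in seq_along(labs)) {
    for (s in seq_len(nsubj)) {
      acc <- c()
      for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
        for (k in seq_len(dims[3])) {
          if (labels[i, j, k] == labs[li]) {
            v <- map4d[i, j, k, s]
            if (v != 0) acc <- c(acc, v)
          }
        }
      out[li, s] <- if (length(acc)) mean(acc) else NA_real_
    }
  }
  out
}

# random labeled fixture for oracle-equivalence checks
random_skeleton_fixture <- function(seed, nRegions = 3, nSubj = 4,
                                    side = 8, zeroFrac = 0.1) {
  set.seed(seed)
  vals <- matrix(runif(nRegions * nSubj, 0.2, 0.9), nRegions, nSubj,
                 dimnames = list(paste0("r", seq_len(nRegions)),
                                 paste0("s", seq_len(nSubj))))
  counts <- setNames(sample(3:10, nRegions, replace = TRUE), rownames(vals))
  sim <- simulateSkeletonVolumes(counts, vals, voxelNoiseSD = 0.05,
                                 seed = seed + 1, dim = rep(side, 3))
  # sprinkle exact zeros inside labels to exercise the exclusion rule
  for (m in names(sim$maps)) {
    lab_idx <- which(sim$labels != 0)
    nvox <- prod(dim(sim$labels))
    for (s in seq_len(nSubj)) {
      kill <- sample(lab_idx, ceiling(zeroFrac * length(lab_idx)))
      sim$maps[[m]][(s - 1) * nvox + kill] <- 0
    }
  }
  sim
}
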