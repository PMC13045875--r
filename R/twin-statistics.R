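#' Residualize regional metrics on age and sex
#'
#' Per region and metric, fits a linear model of the value on age and sex
#' across all retained subjects (MZ and DZ pooled) and keeps the residuals.
#' Missing cells stay missing; residuals are mean-zero and orthogonal to age
#' by construction.
#'
#' @param x A [RegionalMetrics] whose `colData` carries `age` and `sex`.
#' @return A [RegionalMetrics] of residuals (metadata flag `adjusted`).
#' @export
adjustAgeSex <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("age", "sex") %in% names(cd)))
    stop("colData must carry age and sex; attach a roster first")
  if (anyNA(cd$age) || anyNA(cd$sex)) {
    bad <- rownames(cd)[is.na(cd$age) | is.na(cd$sex)]
    stop("missing age/sex covariate for subject(s): ",
         paste(bad, collapse = ", "))
  }
  age <- cd$age
  sex <- factor(cd$sex)
  for (m in metricNames(x)) {
    a <- SummarizedExperiment::assay(x, m)
    res <- t(apply(a, 1, function(y) {
      if (sum(!is.na(y)) < 4) return(y * NA_real_)
      residuals(lm(y ~ age + sex, na.action = na.exclude))
    }))
    dimnames(res) <- dimnames(a)
    SummarizedExperiment::assay(x, m) <- res
  }
  S4Vectors::metadata(x)$adjusted <- TRUE
  x
}

double_entry_r <- function(v1, v2) {
  ok <- !is.na(v1) & !is.na(v2)
  n <- sum(ok)
  if (n < 3) return(c(r = NA_real_, n_pairs = n))
  x <- c(v1[ok], v2[ok]); y <- c(v2[ok], v1[ok])
  if (sd(x) == 0) return(c(r = 1, n_pairs = n))
  c(r = cor(x, y), n_pairs = n)
}

#' Twin correlations per region, metric and zygosity
#'
#' Computes the double-entry Pearson correlation for each region/metric and
#' zygosity group: every complete pair contributes both orderings
#' (twin1, twin2) and (twin2, twin1), so the estimate is invariant to
#' within-pair labeling and equals the ANOVA intraclass correlation of the
#' stacked data. Pairs with a missing member value for a cell are dropped
#' pairwise; groups with fewer than 3 complete pairs yield `NA`.
#'
#' @param x A [RegionalMetrics], typically the output of [adjustAgeSex()];
#'   `colData` must carry `pair_id`, `twin_index` and `zygosity`.
#' @return `data.frame` with columns `region`, `metric`, `zygosity`, `r`,
#'   `n_pairs`.
#' @export
twinCorrelations <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  need <- c("pair_id", "twin_index", "zygosity")
  if (!all(need %in% names(cd)))
    stop("colData must carry ", paste(need, collapse = ", "))
  t1 <- which(cd$twin_index == 1L)
  t2 <- which(cd$twin_index == 2L)
  t2 <- t2[match(cd$pair_id[t1], cd$pair_id[t2])]
  zyg <- as.character(cd$zygosity[t1])
  out <- list()
  for (m in metricNames(x)) {
    a <- SummarizedExperiment::assay(x, m)
    for (z in c("MZ", "DZ")) {
      inZ <- zyg == z
      if (!any(inZ)) next
      est <- t(apply(a, 1, function(y)
        double_entry_r(y[t1[inZ]], y[t2[inZ]])))
      out[[paste(m, z)]] <- data.frame(
        region = rownames(a), metric = m, zygosity = z,
        r = est[, "r"], n_pairs = as.integer(est[, "n_pairs"]),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (anyNA(res$r))
    twin_log("twin correlations: %d estimates dropped (< 3 complete pairs)",
             sum(is.na(res$r)))
  res
}

#' Compare an MZ and a DZ correlation (Fisher z)
#'
#' Fisher z-transforms both correlations and tests MZ > DZ one-sided:
#' z = (atanh(r_mz) - atanh(r_dz)) / sqrt(1/(n_mz - 3) + 1/(n_dz - 3)).
#'
#' @param r_mz,n_mz,r_dz,n_dz Correlations and pair counts (n >= 4,
#'   |r| < 1).
#' @return `data.frame` with `z`, `p` (one-sided, MZ greater) and
#'   `direction` (`"MZ>DZ"` or `"DZ>=MZ"`).
#' @examples
#' compareTwinCorrelations(0.81, 33, 0.37, 48)
#' @export
compareTwinCorrelations <- function(r_mz, n_mz, r_dz, n_dz) {
  if (any(abs(c(r_mz, r_dz)) >= 1))
    stop("|r| = 1 has an infinite Fisher transform")
  if (any(c(n_mz, n_dz) < 4)) stop("need at least 4 pairs per group")
  z <- (atanh(r_mz) - atanh(r_dz)) / sqrt(1 / (n_mz - 3) + 1 / (n_dz - 3))
  data.frame(z = z, p = pnorm(z, lower.tail = FALSE),
             direction = ifelse(z > 0, "MZ>DZ", "DZ>=MZ"),
             stringsAsFactors = FALSE)
}

#' Summarize the correlations of one metric/zygosity
#'
#' Arithmetic mean, minimum and maximum over regional estimates, rounded
#' half-up to 2 decimals for reporting.
#'
#' @param r Numeric vector of regional correlations (`NA` dropped).
#' @return Named numeric `mean`, `min`, `max`.
#' @export
summarizeMetricCorrelations <- function(r) {
  r <- r[!is.na(r)]
  if (!length(r)) stop("no correlation estimates to summarize")
  roundHalfUp(c(mean = mean(r), min = min(r), max = max(r)), 2)
}

#' Demographic comparability of the zygosity groups
#'
#' Chi-squared test (no continuity correction) on the zygosity x
#' pair-sex-composition (male-male / female-female / opposite-sex)
#' contingency table, and an unpaired two-sided Student t-test on pair age by
#' zygosity, with group means/SDs.
#'
#' @param roster Pair roster; only retained pairs are used.
#' @return List with `sex` (`statistic`, `df`, `p`, `table`) and `age`
#'   (`statistic`, `df`, `p`, `means`, `sds`).
#' @export
demographicsTests <- function(roster) {
  roster <- retainedPairs(roster)
  if (length(unique(roster$zygosity)) < 2)
    stop("both zygosity groups must be non-empty")
  if (any(table(roster$zygosity) < 2))
    stop("each zygosity group needs at least 2 pairs for the t-test")
  comp <- ifelse(roster$sex_1 != roster$sex_2, "OS",
                 ifelse(roster$sex_1 == "M", "MM", "FF"))
  tab <- table(factor(roster$zygosity, c("MZ", "DZ")),
               factor(comp, c("MM", "FF", "OS")))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  ages <- split(roster$age, roster$zygosity)
  if (var(roster$age) == 0) {
    # degenerate but well-defined: identical ages everywhere
    tt <- list(statistic = 0, parameter = nrow(roster) - 2, p.value = 1)
  } else {
    tt <- t.test(roster$age ~ factor(roster$zygosity, c("MZ", "DZ")),
                 var.equal = TRUE)
  }
  list(
    sex = list(statistic = unname(chi$statistic), df = unname(chi$parameter),
               p = chi$p.value, table = tab),
    age = list(statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               means = vapply(ages, mean, numeric(1)),
               sds = vapply(ages, sd, numeric(1))))
}

#' Wide per-region correlation table with MZ/DZ comparison
#'
#' Joins the MZ and DZ estimates of [twinCorrelations()] and appends the
#' Fisher-z comparison, mirroring the left half of a twin-study results
#' table.
#'
#' @param cors Long output of [twinCorrelations()].
#' @return `data.frame` with columns `region`, `metric`, `r_mz`, `n_mz`,
#'   `r_dz`, `n_dz`, `z`, `p`.
#' @export
correlationTable <- function(cors) {
  mz <- cors[cors$zygosity == "MZ", c("region", "metric", "r", "n_pairs")]
  dz <- cors[cors$zygosity == "DZ", c("region", "metric", "r", "n_pairs")]
  names(mz)[3:4] <- c("r_mz", "n_mz")
  names(dz)[3:4] <- c("r_dz", "n_dz")
  w <- merge(mz, dz, by = c("region", "metric"), sort = FALSE)
  ok <- !is.na(w$r_mz) & !is.na(w$r_dz) &
    abs(w$r_mz) < 1 & abs(w$r_dz) < 1
  w$z <- w$p <- NA_real_
  if (any(ok)) {
    cmpr <- compareTwinCorrelations(w$r_mz[ok], w$n_mz[ok],
                                    w$r_dz[ok], w$n_dz[ok])
    w$z[ok] <- cmpr$z
    w$p[ok] <- cmpr$p
  }
  w
}
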