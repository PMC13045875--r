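#' Construct a RegionalMetrics object
#'
#' @param assays Named list of region x subject matrices; names must be among
#'   `FA`, `MD`, `AD`, `RD` and all matrices must share dimnames.
#' @param subjects `data.frame` of per-subject metadata (one row per subject,
#'   in assay column order), typically from [rosterSubjects()]. May be omitted
#'   for bare extraction output; twin operations then require attaching a
#'   roster later via [attachRoster()].
#' @return A [RegionalMetrics] object.
#' @export
RegionalMetrics <- function(assays, subjects = NULL) {
  assays <- lapply(assays, as.matrix)
  if (is.null(subjects)) {
    subjects <- S4Vectors::DataFrame(row.names = colnames(assays[[1]]))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = subjects)
  new("RegionalMetrics", se)
}

#' @describeIn RegionalMetrics Attach (or replace) per-subject twin metadata.
#'   `roster` may be a pair roster (expanded via [rosterSubjects()]) or an
#'   already-expanded subject table with a `subject_id` column matching the
#'   object's subjects.
#' @param x A `RegionalMetrics` object.
#' @param roster Pair roster or subject table.
#' @export
attachRoster <- function(x, roster) {
  if ("excluded_reason" %in% names(roster)) roster <- rosterSubjects(roster)
  if (!"subject_id" %in% names(roster))
    stop("roster must carry a subject_id column")
  miss <- setdiff(colnames(x), roster$subject_id)
  if (length(miss))
    stop("roster is missing subjects: ", paste(miss, collapse = ", "))
  roster <- roster[match(colnames(x), roster$subject_id), , drop = FALSE]
  SummarizedExperiment::colData(x) <- S4Vectors::DataFrame(
    roster, row.names = roster$subject_id)
  validObject(x)
  x
}

#' @describeIn RegionalMetrics Region names (rownames).
#' @export
regionNames <- function(x) rownames(x)

#' @describeIn RegionalMetrics Names of the diffusion metrics present.
#' @export
metricNames <- function(x) SummarizedExperiment::assayNames(x)

setMethod("show", "RegionalMetrics", function(object) {
  cat("RegionalMetrics:", nrow(object), "regions x", ncol(object),
      "subjects\n  metrics:", paste(metricNames(object), collapse = ", "), "\n")
  cd <- SummarizedExperiment::colData(object)
  if ("zygosity" %in% names(cd)) {
    tab <- table(cd$zygosity) / 2
    cat("  pairs:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  nmiss <- sum(vapply(SummarizedExperiment::assays(object),
                      function(a) sum(is.na(a)), numeric(1)))
  if (nmiss) cat("  missing cells:", nmiss, "\n")
  invisible(NULL)
})

#' Long-format CSV round trip for regional metric tables
#'
#' The on-disk interchange format is a UTF-8 CSV with one row per
#' (subject, region, metric) cell: columns `subject_id`, `pair_id`,
#' `twin_index`, `region`, `metric`, `value`. Missing cells are written with
#' an empty value field.
#'
#' @param x A [RegionalMetrics] object.
#' @param path File path.
#' @return `writeRegionalTable()` invisibly returns `path`;
#'   `readRegionalTable()` returns a [RegionalMetrics] (metadata columns
#'   beyond `pair_id`/`twin_index` are restored via `roster` when given).
#' @param roster Optional pair roster to attach on read.
#' @export
writeRegionalTable <- function(x, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  long <- do.call(rbind, lapply(metricNames(x), function(m) {
    a <- SummarizedExperiment::assay(x, m)
    data.frame(subject_id = rep(colnames(a), each = nrow(a)),
               region = rep(rownames(a), times = ncol(a)),
               metric = m, value = as.vector(a),
               stringsAsFactors = FALSE)
  }))
  if (all(c("pair_id", "twin_index") %in% names(cd))) {
    long$pair_id <- cd[long$subject_id, "pair_id"]
    long$twin_index <- cd[long$subject_id, "twin_index"]
    long <- long[, c("subject_id", "pair_id", "twin_index",
                     "region", "metric", "value")]
  }
  write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeRegionalTable
#' @export
readRegionalTable <- function(path, roster = NULL) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "region", "metric", "value")
  if (!all(need %in% names(long)))
    stop("regional table must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(long[, c("subject_id", "region", "metric")]))
    stop("duplicated (subject, region, metric) cells in ", path)
  subjects <- unique(long$subject_id)
  regions <- unique(long$region)
  assays <- lapply(split(long, long$metric), function(d) {
    m <- matrix(NA_real_, length(regions), length(subjects),
                dimnames = list(regions, subjects))
    m[cbind(d$region, d$subject_id)] <- d$value
    m
  })
  assays <- assays[intersect(VALID_METRICS, names(assays))]
  x <- RegionalMetrics(assays)
  if (!is.null(roster)) x <- attachRoster(x, roster)
  x
}

#' JHU ICBM-DTI-81 white-matter label table
#'
#' The 48 integer labels of the standard JHU ICBM-DTI-81 white-matter atlas,
#' with the abbreviated region names used throughout the package (bilateral
#' regions carry `_R`/`_L` suffixes).
#'
#' @return Named character vector: names are label integers `1:48`, values
#'   region abbreviations.
#' @export
jhuRegionLabels <- function() {
  setNames(c(
    "MCP", "PCT", "gCC", "bCC", "sCC", "FX",
    "CST_R", "CST_L", "ML_R", "ML_L", "ICP_R", "ICP_L",
    "SCP_R", "SCP_L", "CP_R", "CP_L",
    "ALIC_R", "ALIC_L", "PLIC_R", "PLIC_L", "RIC_R", "RIC_L",
    "ACR_R", "ACR_L", "SCR_R", "SCR_L", "PCR_R", "PCR_L",
    "PTR_R", "PTR_L", "SS_R", "SS_L", "EC_R", "EC_L",
    "CgC_R", "CgC_L", "CgH_R", "CgH_L", "FX/ST_R", "FX/ST_L",
    "SLF_R", "SLF_L", "SFOF_R", "SFOF_L", "UF_R", "UF_L",
    "TAP_R", "TAP_L"), as.character(1:48))
}

#' @describeIn jhuRegionLabels The six regions conventionally dropped for
#'   poor skeleton representation in the brainstem/cerebellum (middle
#'   cerebellar peduncle, pontine crossing tract, bilateral medial lemniscus
#'   and inferior cerebellar peduncle), leaving 42 analysable regions.
#' @export
defaultRegionExclusions <- function() {
  c("MCP", "PCT", "ML_R", "ML_L", "ICP_R", "ICP_L")
}

#' Published regional twin correlations and variance components
#'
#' The published per-region results for an 81-pair (33 MZ / 48 DZ) twin
#' cohort: age/sex-adjusted MZ and DZ correlations, the one-sided p-value of
#' their comparison, the selected biometric model and the fitted standardized
#' variance components, for 42 white-matter regions and the four diffusion
#' metrics. Shipped as a plain-text fixture so in-package analyses (model
#' refits, summary statistics, report rendering) can run against the printed
#' numbers.
#'
#' @return `data.frame` with columns `region`, `metric`, `r_mz`, `r_dz`,
#'   `p_value`, `model`, `A`, `C`, `D`, `A_plus_D`, `G`, `E`, `total`
#'   (component cells not estimated under a model are `NA`).
#' @examples
#' head(referenceTwinCorrelations())
#' @export
referenceTwinCorrelations <- function() {
  path <- system.file("extdata", "reference_twin_correlations.csv",
                      package = "twinDTI", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @describeIn referenceTwinCorrelations The same table reshaped as a
#'   generator truth: columns `region`, `metric`, `model`, `A`, `C`, `D`,
#'   `E` with unestimated components set to 0, suitable for
#'   [twinSimConfig()]'s `components` argument.
#' @export
referenceComponents <- function() {
  ref <- referenceTwinCorrelations()
  cmp <- ref[, c("region", "metric", "model", "A", "C", "D", "E")]
  cmp$C[is.na(cmp$C)] <- 0
  cmp$D[is.na(cmp$D)] <- 0
  # a handful of printed rows label the model ADE while reporting the
  # C column; force the confounding rule so the config validates
  cmp$C[cmp$model == "ADE"] <- 0
  cmp$D[cmp$model == "ACE"] <- 0
  tot <- cmp$A + cmp$C + cmp$D + cmp$E
  cmp[, c("A", "C", "D", "E")] <- cmp[, c("A", "C", "D", "E")] / tot
  cmp
}
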