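#' Run the twin-heritability pipeline end to end
#'
#' Orchestrates the stages simulate/extract -> harmonize -> adjust ->
#' correlate -> fit -> report, writing every intermediate artifact and a
#' manifest to `outDir`. Reruns with the same configuration and seed are
#' bit-identical.
#'
#' The configuration is a list (or a YAML/JSON file path) with fields:
#' \describe{
#'   \item{mode}{`"synthetic"` (simulate a cohort), `"from_volumes"`
#'     (NIfTI skeleton maps + label atlas + roster CSV), `"from_table"`
#'     (long-format regional CSV + roster CSV), or `"from_correlations"`
#'     (a per-region correlation CSV with `region`, `metric`, `r_mz`,
#'     `r_dz` and optional `n_mz`, `n_dz`; goes straight to model
#'     fitting).}
#'   \item{seed}{Integer; required for synthetic mode.}
#'   \item{harmonize}{Logical stage toggle (default `TRUE`; ignored in
#'     `from_correlations` mode).}
#'   \item{paths}{Mode-dependent input paths: `maps` (named list per
#'     metric), `atlas`, `roster`, `table`, `correlations`.}
#'   \item{n_mz,n_dz}{Pair counts assumed for `from_correlations` input
#'     lacking count columns (defaults 33 and 48).}
#'   \item{exclusions}{Synthetic mode: named exclusion counts for
#'     [buildRoster()].}
#'   \item{sim}{Synthetic mode: named list of [twinSimConfig()] overrides.}
#' }
#'
#' @param config List or path to a YAML/JSON configuration file.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with `report` (the per-region results
#'   `data.frame`), `summary` (rendered report lines) and `manifest`.
#' @examples
#' \donttest{
#' cfg <- list(mode = "from_correlations",
#'             paths = list(correlations = system.file(
#'               "extdata", "reference_twin_correlations.csv",
#'               package = "twinDTI")))
#' res <- runTwinPipeline(cfg, outDir = tempfile("twinrun"))
#' head(res$report)
#' }
#' @export
runTwinPipeline <- function(config, outDir = "twinDTI_out") {
  if (is.character(config) && length(config) == 1) config <- readConfig(config)
  mode <- match.arg(config$mode,
                    c("synthetic", "from_volumes", "from_table",
                      "from_correlations"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name) written <<- c(written, name)

  corTab <- NULL
  if (mode == "from_correlations") {
    ct <- read.csv(config$paths$correlations, stringsAsFactors = FALSE)
    if (!all(c("region", "metric", "r_mz", "r_dz") %in% names(ct)))
      stop("stage correlate: correlation input lacks region/metric/r_mz/r_dz")
    if (is.null(ct$n_mz)) ct$n_mz <- config$n_mz %||% 33
    if (is.null(ct$n_dz)) ct$n_dz <- config$n_dz %||% 48
    ok <- !is.na(ct$r_mz) & !is.na(ct$r_dz)
    ct$z <- ct$p <- NA_real_
    cmpr <- compareTwinCorrelations(ct$r_mz[ok], ct$n_mz[ok],
                                    ct$r_dz[ok], ct$n_dz[ok])
    ct$z[ok] <- cmpr$z; ct$p[ok] <- cmpr$p
    corTab <- ct[, c("region", "metric", "r_mz", "n_mz",
                     "r_dz", "n_dz", "z", "p")]
  } else {
    if (mode == "synthetic") {
      if (is.null(config$seed)) stop("synthetic mode requires a seed")
      simArgs <- config$sim %||% list()
      simArgs$seed <- config$seed
      cfg <- do.call(twinSimConfig, simArgs)
      roster <- buildRoster(cfg, exclusions = unlist(
        config$exclusions %||% c(psychiatric = 0)))
      rm <- simulateTwinMetrics(roster, cfg)
      write.csv(roster, file.path(outDir, "roster.csv"), row.names = FALSE)
      emit("roster.csv")
    } else if (mode == "from_volumes") {
      vols <- readSkeletonMaps(unlist(config$paths$maps),
                               config$paths$atlas)
      roster <- read.csv(config$paths$roster, stringsAsFactors = FALSE)
      subj <- rosterSubjects(roster)
      rm <- extractRegionalMeans(vols$maps, vols$labels,
                                 subjects = subj$subject_id)
      rm <- attachRoster(rm, roster)
    } else {
      roster <- read.csv(config$paths$roster, stringsAsFactors = FALSE)
      rm <- readRegionalTable(config$paths$table, roster = roster)
    }
    writeRegionalTable(rm, file.path(outDir, "regional_metrics.csv"))
    emit("regional_metrics.csv")

    if (isTRUE(config$harmonize %||% TRUE)) {
      h <- harmonizeMetrics(rm)
      rm <- h$data
      for (m in names(h$models)) {
        f <- sprintf("combat_model_%s.json", m)
        writeCombatModel(h$models[[m]], file.path(outDir, f))
        emit(f)
      }
      writeRegionalTable(rm, file.path(outDir, "harmonized_metrics.csv"))
      emit("harmonized_metrics.csv")
    }

    resid <- adjustAgeSex(rm)
    cors <- twinCorrelations(resid)
    corTab <- correlationTable(cors)
  }
  write.csv(corTab, file.path(outDir, "correlations.csv"), row.names = FALSE)
  emit("correlations.csv")

  report <- fitComponentsTable(corTab)
  write.csv(report, file.path(outDir, "components.csv"), row.names = FALSE)
  emit("components.csv")

  summaryLines <- renderTwinReport(report)
  writeLines(summaryLines, file.path(outDir, "report.txt"))
  emit("report.txt")

  manifest <- list(
    package = "twinDTI",
    version = as.character(packageVersion("twinDTI")),
    mode = mode,
    seed = config$seed %||% NULL,
    config = config,
    files = lapply(setNames(nm = sort(unique(written))), function(f)
      list(md5 = unname(tools::md5sum(file.path(outDir, f))))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(report = report, summary = summaryLines,
                 manifest = manifest))
}

#' Render the plain-text summary report
#'
#' Emits, per metric: mean/min/max of the MZ and DZ correlations (half-up
#' rounded to 2 decimals), the regions where the DZ correlation strictly
#' exceeds the MZ correlation (the "inverse pattern"), and the regions with
#' near-zero heritability (G <= `gNearZero`).
#'
#' @param report Output of [fitComponentsTable()] (or any table with
#'   `region`, `metric`, `r_mz`, `r_dz`, `G`).
#' @param gNearZero Threshold under which G counts as essentially zero.
#' @return Character vector of report lines.
#' @export
renderTwinReport <- function(report, gNearZero = 0.05) {
  lines <- character()
  for (m in intersect(VALID_METRICS, unique(report$metric))) {
    d <- report[report$metric == m, ]
    smz <- summarizeMetricCorrelations(d$r_mz)
    sdz <- summarizeMetricCorrelations(d$r_dz)
    lines <- c(lines, sprintf(
      "%s: MZ mean %.2f (range %.2f to %.2f); DZ mean %.2f (range %.2f to %.2f)",
      m, smz["mean"], smz["min"], smz["max"],
      sdz["mean"], sdz["min"], sdz["max"]))
    inv <- d$region[!is.na(d$r_mz) & !is.na(d$r_dz) & d$r_dz > d$r_mz]
    lines <- c(lines, sprintf("%s: inverse pattern (r_dz > r_mz): %s", m,
                              if (length(inv)) paste(inv, collapse = ", ")
                              else "none"))
    if ("G" %in% names(d)) {
      nz <- d$region[!is.na(d$G) & d$G <= gNearZero]
      lines <- c(lines, sprintf("%s: near-zero heritability (G <= %.2f): %s",
                                m, gNearZero,
                                if (length(nz)) paste(nz, collapse = ", ")
                                else "none"))
    }
  }
  lines
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return Configuration list for [runTwinPipeline()].
#' @export
readConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file")
}
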