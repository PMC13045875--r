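combat_design <- function(batch, covariates) {
  batch <- factor(batch)
  if (nlevels(batch) < 2)
    stop("only one batch present: skip harmonization for single-scanner data")
  if (any(table(batch) < 2))
    stop("every batch needs at least two subjects")
  bd <- model.matrix(~ -1 + batch)
  colnames(bd) <- levels(batch)
  covm <- NULL
  if (!is.null(covariates) && length(covariates)) {
    covariates <- as.data.frame(covariates)
    covm <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  X <- cbind(bd, covm)
  if (qr(X)$rank < ncol(X))
    stop("confounded design: a covariate is collinear with batch")
  list(batch = batch, X = X, nBatchCols = ncol(bd),
       covNames = colnames(covm) %||% character())
}

# EB iterative conditional update for one batch (parametric priors),
# feature-wise observation counts n may vary with missingness
eb_solve <- function(gHat, d2Hat, Z, inBatch, conv = 1e-4, maxit = 100) {
  gBar <- mean(gHat)
  tau2 <- var(gHat)
  m <- mean(d2Hat); s2 <- var(d2Hat)
  aPrior <- (2 * s2 + m^2) / s2
  bPrior <- (m * s2 + m^3) / s2
  n <- rowSums(!is.na(Z[, inBatch, drop = FALSE]))
  gOld <- gHat; d2Old <- d2Hat
  it <- 0
  repeat {
    it <- it + 1
    gNew <- (n * tau2 * gHat + d2Old * gBar) / (n * tau2 + d2Old)
    sum2 <- rowSums((Z[, inBatch, drop = FALSE] - gNew)^2, na.rm = TRUE)
    d2New <- (0.5 * sum2 + bPrior) / (n / 2 + aPrior - 1)
    change <- max(abs(gNew - gOld) / abs(gOld), abs(d2New - d2Old) / d2Old)
    gOld <- gNew; d2Old <- d2New
    if (is.na(change) || change < conv || it >= maxit) break
  }
  list(gammaStar = gNew, delta2Star = d2New, iterations = it,
       priors = list(gammaBar = gBar, tau2 = tau2,
                     aPrior = aPrior, bPrior = bPrior))
}

#' Fit an empirical-Bayes batch-harmonization (ComBat) model
#'
#' Location/scale harmonization with parametric empirical-Bayes shrinkage:
#' each feature is standardized by its covariate-adjusted grand mean and
#' pooled variance, per-batch location and scale estimates are shrunk toward
#' moment-matched normal / inverse-gamma priors by iterative conditional
#' updates (to a relative change below `conv`), and the batch effect is then
#' removed while the fitted covariate (age, sex) structure is preserved.
#' Missing cells are excluded feature-wise from every estimation step and
#' pass through [applyComBat()] unmodified.
#'
#' @param mat Features x subjects numeric matrix (e.g. one assay of a
#'   [RegionalMetrics]); `NA` allowed.
#' @param batch Subject batch (scanner) labels, length `ncol(mat)`.
#' @param covariates `data.frame` of biological covariates to preserve (one
#'   row per subject), e.g. `age` (numeric) and `sex` (factor); may be `NULL`.
#' @param conv,maxit Empirical-Bayes convergence tolerance and iteration cap.
#' @return A [CombatModel].
#' @seealso [applyComBat()], [harmonizeMetrics()]
#' @export
fitComBat <- function(mat, batch, covariates = NULL,
                      conv = 1e-4, maxit = 100) {
  mat <- as.matrix(mat)
  des <- combat_design(batch, covariates)
  X <- des$X; nb <- des$nBatchCols
  levelsB <- levels(des$batch)
  nPerBatch <- as.vector(table(des$batch))

  G <- nrow(mat)
  feats <- rownames(mat) %||% as.character(seq_len(G))
  # feature-wise OLS on the full (batch + covariate) design
  B <- matrix(NA_real_, G, ncol(X), dimnames = list(feats, colnames(X)))
  varPooled <- numeric(G)
  nTot <- ncol(mat)
  for (g in seq_len(G)) {
    ok <- !is.na(mat[g, ])
    if (sum(ok) <= ncol(X))
      stop("feature ", feats[g], " has too few observed values to fit")
    fit <- lm.fit(X[ok, , drop = FALSE], mat[g, ok])
    B[g, ] <- fit$coefficients
    varPooled[g] <- sum(fit$residuals^2) / sum(ok)
  }
  if (any(!is.finite(varPooled)) || any(varPooled <= 0))
    stop("a feature is constant within every batch; cannot standardize")
  grandMean <- as.vector(B[, seq_len(nb), drop = FALSE] %*%
                           (nPerBatch / nTot))
  covCoef <- B[, -seq_len(nb), drop = FALSE]

  standMean <- grandMean +
    if (ncol(covCoef)) covCoef %*% t(X[, -seq_len(nb), drop = FALSE]) else 0
  Z <- (mat - standMean) / sqrt(varPooled)

  gammaStar <- delta2Star <- matrix(
    NA_real_, G, length(levelsB), dimnames = list(feats, levelsB))
  priors <- list(); iters <- numeric(length(levelsB))
  for (b in seq_along(levelsB)) {
    inB <- which(des$batch == levelsB[b])
    gHat <- rowMeans(Z[, inB, drop = FALSE], na.rm = TRUE)
    d2Hat <- apply(Z[, inB, drop = FALSE], 1, var, na.rm = TRUE)
    sol <- eb_solve(gHat, d2Hat, Z, inB, conv = conv, maxit = maxit)
    gammaStar[, b] <- sol$gammaStar
    delta2Star[, b] <- sol$delta2Star
    priors[[levelsB[b]]] <- sol$priors
    iters[b] <- sol$iterations
  }
  new("CombatModel",
      features = feats, batches = levelsB, covariates = des$covNames,
      grandMean = setNames(grandMean, feats), covCoef = covCoef,
      varPooled = setNames(varPooled, feats),
      gammaStar = gammaStar, delta2Star = delta2Star,
      priors = priors, iterations = setNames(iters, levelsB))
}

#' Apply a fitted ComBat model to a feature matrix
#'
#' Standardizes with the model's grand mean, covariate fit and pooled
#' variance, removes the EB-shrunk batch location/scale, and restores the
#' grand mean and covariate structure. Row order and shape are preserved;
#' `NA` cells pass through.
#'
#' @param model A [CombatModel] from [fitComBat()].
#' @param mat Features x subjects matrix whose rownames match the model's
#'   features.
#' @param batch Subject batch labels; all must be known to the model.
#' @param covariates Covariate `data.frame`, same columns as used at fit.
#' @return Harmonized matrix, same dimnames as `mat`.
#' @export
applyComBat <- function(model, mat, batch, covariates = NULL) {
  stopifnot(is(model, "CombatModel"))
  mat <- as.matrix(mat)
  feats <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  if (!all(feats %in% model@features))
    stop("matrix features not covered by the model: ",
         paste(setdiff(feats, model@features), collapse = ", "))
  batch <- as.character(batch)
  if (!all(batch %in% model@batches))
    stop("unseen batch label(s): ",
         paste(setdiff(batch, model@batches), collapse = ", "))
  i <- match(feats, model@features)
  covPart <- 0
  if (length(model@covariates)) {
    covariates <- as.data.frame(covariates)
    Xc <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    if (!all(colnames(Xc) %in% colnames(model@covCoef)))
      stop("covariate columns do not match the fitted model")
    Xc <- Xc[, colnames(model@covCoef), drop = FALSE]
    covPart <- model@covCoef[i, , drop = FALSE] %*% t(Xc)
  }
  standMean <- model@grandMean[i] + covPart
  Z <- (mat - standMean) / sqrt(model@varPooled[i])
  bIdx <- match(batch, model@batches)
  adj <- (Z - model@gammaStar[i, bIdx, drop = FALSE]) /
    sqrt(model@delta2Star[i, bIdx, drop = FALSE])
  adj * sqrt(model@varPooled[i]) + standMean
}

#' Harmonize every metric of a RegionalMetrics object
#'
#' Fits and applies ComBat per metric (each assay is one feature matrix of
#' regions x subjects), taking the batch from the `scanner` column and the
#' preserved covariates from the `age` and `sex` columns of `colData`.
#'
#' @param x A [RegionalMetrics] with `scanner`, `age`, `sex` in `colData`.
#' @param ... Passed to [fitComBat()].
#' @return List with `data` (the harmonized [RegionalMetrics]) and `models`
#'   (named list of per-metric [CombatModel]s).
#' @export
harmonizeMetrics <- function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  need <- c("scanner", "age", "sex")
  if (!all(need %in% names(cd)))
    stop("colData must carry ", paste(need, collapse = ", "))
  cov <- data.frame(age = cd$age, sex = factor(cd$sex))
  models <- list()
  for (m in metricNames(x)) {
    mod <- fitComBat(SummarizedExperiment::assay(x, m), cd$scanner, cov, ...)
    SummarizedExperiment::assay(x, m) <- applyComBat(
      mod, SummarizedExperiment::assay(x, m), cd$scanner, cov)
    models[[m]] <- mod
  }
  S4Vectors::metadata(x)$harmonized <- TRUE
  list(data = x, models = models)
}

setMethod("show", "CombatModel", function(object) {
  cat("CombatModel:", length(object@features), "features,",
      length(object@batches), "batches (",
      paste(object@batches, collapse = ", "), ")\n")
  if (length(object@covariates))
    cat("  preserved covariates:", paste(object@covariates, collapse = ", "),
        "\n")
  cat("  EB iterations:", paste(object@iterations, collapse = ", "), "\n")
  invisible(NULL)
})

#' Serialize / restore a ComBat model as JSON
#'
#' @param model A [CombatModel].
#' @param path JSON file path.
#' @return `writeCombatModel()` invisibly returns `path`;
#'   `readCombatModel()` returns the restored [CombatModel].
#' @export
writeCombatModel <- function(model, path) {
  obj <- list(features = model@features, batches = model@batches,
              covariates = model@covariates,
              grandMean = unname(model@grandMean),
              covCoef = model@covCoef, varPooled = unname(model@varPooled),
              gammaStar = model@gammaStar, delta2Star = model@delta2Star,
              priors = model@priors, iterations = unname(model@iterations))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCombatModel
#' @export
readCombatModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(o$features, o$batches)
    m
  }
  cc <- as.matrix(o$covCoef)
  rownames(cc) <- o$features
  if (is.null(colnames(cc)) && length(o$covariates) == ncol(cc))
    colnames(cc) <- o$covariates
  new("CombatModel",
      features = o$features, batches = o$batches,
      covariates = as.character(o$covariates),
      grandMean = setNames(o$grandMean, o$features), covCoef = cc,
      varPooled = setNames(o$varPooled, o$features),
      gammaStar = mk(o$gammaStar), delta2Star = mk(o$delta2Star),
      priors = o$priors, iterations = setNames(o$iterations, o$batches))
}
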