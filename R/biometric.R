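#' Choose between ACE and ADE from the twin correlation pattern
#'
#' C (shared environment) and D (dominance) cannot be estimated together
#' from twins reared together, so one fully parameterized model is chosen
#' per trait: ADE when the DZ correlation falls below half the MZ
#' correlation (the classical signature of non-additive genetic variance),
#' otherwise ACE. Ties go to ACE.
#'
#' @param r_mz,r_dz Twin correlations.
#' @return `"ACE"` or `"ADE"` (vectorized).
#' @examples
#' selectTwinModel(0.89, 0.54)  # ACE
#' selectTwinModel(0.81, 0.37)  # ADE
#' @export
selectTwinModel <- function(r_mz, r_dz) {
  stopifnot(is.finite(r_mz), is.finite(r_dz))
  ifelse(r_dz < r_mz / 2, "ADE", "ACE")
}

#' Model-implied twin correlations
#'
#' The biometric covariance algebra: MZ co-twins share all additive and
#' dominance variance, DZ co-twins half the additive and a quarter of the
#' dominance variance, and the shared environment fully. Hence
#' r_mz = A + C + D and r_dz = A/2 + C + D/4.
#'
#' @param A,C,D Standardized variance fractions (C used under ACE, D under
#'   ADE).
#' @param model `"ACE"` or `"ADE"`; the confounded component must be 0.
#' @return Named numeric `r_mz`, `r_dz`.
#' @export
expectedTwinCorrelations <- function(A, C = 0, D = 0, model = "ACE") {
  model <- match.arg(model, VALID_MODELS)
  if (model == "ACE" && any(D != 0)) stop("D must be 0 under ACE")
  if (model == "ADE" && any(C != 0)) stop("C must be 0 under ADE")
  c(r_mz = A + C + D, r_dz = A / 2 + C + D / 4)
}

#' Falconer method-of-moments variance components
#'
#' Closed-form solutions of the exactly identified fully parameterized
#' models: under ACE, A = 2(r_mz - r_dz), C = 2 r_dz - r_mz; under ADE,
#' A = 4 r_dz - r_mz, D = 2 r_mz - 4 r_dz; in both, E = 1 - r_mz. No
#' constraints are applied — negative solutions are returned as-is with
#' `interior = FALSE`, and serve as the unconstrained oracle for the ML fit.
#'
#' @param r_mz,r_dz Twin correlations.
#' @param model `"ACE"` or `"ADE"`; default selects via [selectTwinModel()].
#' @param eFloor Minimum admissible E for the interior flag (ML floor).
#' @return `data.frame` row: `model`, `A`, `C`, `D`, `E`, `interior`.
#' @examples
#' falconerComponents(0.89, 0.54, "ACE")  # A=0.70 C=0.19 E=0.11
#' @export
falconerComponents <- function(r_mz, r_dz,
                               model = selectTwinModel(r_mz, r_dz),
                               eFloor = 0.001) {
  model <- match.arg(model, VALID_MODELS)
  if (model == "ACE") {
    A <- 2 * (r_mz - r_dz); C <- 2 * r_dz - r_mz; D <- 0
  } else {
    A <- 4 * r_dz - r_mz; D <- 2 * r_mz - 4 * r_dz; C <- 0
  }
  E <- 1 - r_mz
  data.frame(model = model, A = A, C = C, D = D, E = E,
             interior = A >= 0 & C >= 0 & D >= 0 & E >= eFloor,
             stringsAsFactors = FALSE)
}

# normal-theory discrepancy between the two observed 2x2 within-pair
# correlation matrices and the model-implied ones; weights n - 1 per group.
# rho, r: implied and observed off-diagonals c(mz, dz); zero iff rho == r.
biometric_discrepancy <- function(rho, r, w) {
  rho <- pmin(pmax(rho, -0.9999), 0.9999)
  sum(w * (log(1 - rho^2) + 2 * (1 - rho * r) / (1 - rho^2) -
             log(1 - r^2) - 2))
}

implied_rho <- function(par, model) {
  if (model == "ACE") c(par[1] + par[2], par[1] / 2 + par[2])
  else c(par[1] + par[2], par[1] / 2 + par[2] / 4)
}

# analytic gradient of biometric_discrepancy in the component parameters
biometric_gradient <- function(par, r, w, model) {
  rho <- implied_rho(par, model)
  rho <- pmin(pmax(rho, -0.9999), 0.9999)
  dFdrho <- w * (-2 * rho / (1 - rho^2) +
                   (4 * rho - 2 * r - 2 * r * rho^2) / (1 - rho^2)^2)
  J <- if (model == "ACE") rbind(c(1, 1), c(0.5, 1))
       else rbind(c(1, 1), c(0.5, 0.25))
  as.vector(t(J) %*% dFdrho)
}

#' Constrained maximum-likelihood biometric fit
#'
#' Maximizes the Gaussian likelihood of the MZ and DZ within-pair
#' correlation matrices (2 x 2, unit diagonal) over standardized variance
#' components, with group weights n_mz - 1 and n_dz - 1, subject to
#' A, C, D >= 0 and A + C + D + E = 1 with E >= `eFloor` (E carries
#' measurement error and cannot vanish). Optimization runs a log-barrier
#' quasi-Newton search from five deterministic starting points (best
#' objective wins, ties to smallest A) followed by an active-set polish:
#' components within `pinTol` of zero are pinned and the free coordinates
#' re-optimized without barrier. Because the fully parameterized model is
#' exactly identified, an interior solution reproduces the observed
#' correlations and equals [falconerComponents()] to optimizer precision.
#'
#' @param r_mz,n_mz,r_dz,n_dz Observed correlations (|r| < 1) and pair
#'   counts (>= 4).
#' @param model `"ACE"` or `"ADE"`; default selects via [selectTwinModel()].
#' @param eFloor Lower bound on E.
#' @param pinTol Boundary detection tolerance for the polish step.
#' @return A [BiometricFit].
#' @examples
#' fit <- fitBiometricModel(0.89, 33, 0.54, 48)
#' components(fit)
#' heritability(fit)
#' @export
fitBiometricModel <- function(r_mz, n_mz, r_dz, n_dz,
                              model = selectTwinModel(r_mz, r_dz),
                              eFloor = 0.001, pinTol = 1e-5) {
  model <- match.arg(model, VALID_MODELS)
  if (any(abs(c(r_mz, r_dz)) >= 1))
    stop("|r| = 1: correlation matrix is singular")
  if (any(c(n_mz, n_dz) < 4)) stop("need at least 4 pairs per group")
  w <- c(n_mz - 1, n_dz - 1)
  r <- c(r_mz, r_dz)
  upper <- 1 - eFloor
  obj <- function(par) biometric_discrepancy(implied_rho(par, model), r, w)
  gr <- function(par) biometric_gradient(par, r, w, model)

  # feasible region: par >= 0, sum(par) <= 1 - eFloor
  ui <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  ci <- c(0, 0, -upper)
  starts <- list(c(0.30, 0.30), c(0.60, 0.10), c(0.10, 0.60),
                 c(0.05, 0.05), c(0.45, 0.45))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      constrOptim(s, obj, grad = gr, ui = ui, ci = ci,
                  control = list(reltol = 1e-12, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-8 ||
        (abs(fit$value - best$value) <= 1e-8 && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best)) stop("biometric optimizer failed to converge")

  # active-set polish: candidate solutions with each plausible constraint
  # set active, plus the method-of-moments point when feasible (for the
  # exactly identified model it attains discrepancy 0, the global optimum)
  feasible <- function(p) all(p >= 0) && sum(p) <= upper
  cand <- list(pmin(pmax(best$par, 0), upper))
  for (pin in 1:2) {           # one component pinned at 0
    free <- 3 - pin
    f1 <- function(v) { p <- c(0, 0); p[free] <- v; obj(p) }
    o <- optimize(f1, c(0, upper), tol = 1e-12)
    p <- c(0, 0); p[free] <- o$minimum
    cand <- c(cand, list(p))
  }
  cand <- c(cand, list(c(0, 0)))                 # both pinned
  oE <- optimize(function(a) obj(c(a, upper - a)), c(0, upper),
                 tol = 1e-12)                    # E at its floor
  cand <- c(cand, list(c(oE$minimum, upper - oE$minimum)))
  oI <- optim(best$par, obj, gr, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 1000))
  if (feasible(oI$par)) cand <- c(cand, list(oI$par))
  fal <- falconerComponents(r_mz, r_dz, model, eFloor = eFloor)
  falPar <- c(fal$A, if (model == "ACE") fal$C else fal$D)
  if (feasible(falPar)) cand <- c(cand, list(falPar))

  vals <- vapply(cand, obj, numeric(1))
  ordr <- order(vals, vapply(cand, `[`, numeric(1), 1))
  par <- cand[[ordr[1]]]
  par[par < pinTol & par > 0 &
        vapply(seq_along(par), function(k) {
          q <- par; q[k] <- 0; obj(q) <= vals[ordr[1]] + 1e-12
        }, logical(1))] <- 0

  A <- par[1]
  C <- if (model == "ACE") par[2] else 0
  D <- if (model == "ADE") par[2] else 0
  E <- 1 - A - C - D
  comps <- c(A = A, C = C, D = D, E = E)
  G <- if (model == "ACE") A else A + D
  rho <- implied_rho(par, model)
  new("BiometricFit", model = model, components = comps, G = unname(G),
      observed = c(r_mz = r_mz, n_mz = n_mz, r_dz = r_dz, n_dz = n_dz),
      implied = c(r_mz = rho[1], r_dz = rho[2]),
      objective = obj(par),
      boundary = intersect(
        names(comps)[abs(comps) < pinTol],
        if (model == "ACE") c("A", "C") else c("A", "D")),
      converged = TRUE)
}

#' @describeIn fitBiometricModel Accessor: named components `A, C, D, E`.
#' @param object A [BiometricFit].
#' @export
components <- function(object) object@components

#' @describeIn fitBiometricModel Accessor: heritability G — narrow-sense A
#'   under ACE, broad-sense A + D under ADE.
#' @export
heritability <- function(object) object@G

#' Broad-sense heritability from components
#'
#' @param A,D Standardized additive and dominance fractions.
#' @param model `"ACE"` or `"ADE"`.
#' @return G = A under ACE, A + D under ADE.
#' @export
broadSenseG <- function(A, D = 0, model = "ACE") {
  model <- match.arg(model, VALID_MODELS)
  if (model == "ACE") A else A + D
}

setMethod("show", "BiometricFit", function(object) {
  cc <- object@components
  cat(sprintf("BiometricFit (%s): A=%.3f C=%.3f D=%.3f E=%.3f  G=%.3f\n",
              object@model, cc["A"], cc["C"], cc["D"], cc["E"], object@G))
  ob <- object@observed
  cat(sprintf("  observed r_mz=%.3f (n=%d)  r_dz=%.3f (n=%d)",
              ob["r_mz"], as.integer(ob["n_mz"]),
              ob["r_dz"], as.integer(ob["n_dz"])))
  if (length(object@boundary))
    cat("  [", paste(object@boundary, collapse = ", "), "at bound ]")
  cat("\n")
  invisible(NULL)
})

#' Fit biometric models for every row of a correlation table
#'
#' Applies [selectTwinModel()] and [fitBiometricModel()] row-wise and
#' appends the component estimates, mirroring the right half of a
#' twin-study results table. Rows with missing correlations are skipped
#' (components `NA`).
#'
#' @param corTable Output of [correlationTable()]: columns `region`,
#'   `metric`, `r_mz`, `n_mz`, `r_dz`, `n_dz` (and optionally `z`, `p`).
#' @return `corTable` with added columns `model`, `A`, `C`, `D`,
#'   `A_plus_D`, `G`, `E`, `total`.
#' @export
fitComponentsTable <- function(corTable) {
  n <- nrow(corTable)
  res <- data.frame(model = rep(NA_character_, n), A = NA_real_,
                    C = NA_real_, D = NA_real_, A_plus_D = NA_real_,
                    G = NA_real_, E = NA_real_, total = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(corTable$r_mz[i]) || is.na(corTable$r_dz[i])) next
    fit <- fitBiometricModel(corTable$r_mz[i], corTable$n_mz[i],
                             corTable$r_dz[i], corTable$n_dz[i])
    cc <- components(fit)
    res$model[i] <- fit@model
    res$A[i] <- cc["A"]; res$E[i] <- cc["E"]
    if (fit@model == "ACE") res$C[i] <- cc["C"]
    else { res$D[i] <- cc["D"]; res$A_plus_D[i] <- cc["A"] + cc["D"] }
    res$G[i] <- heritability(fit)
    res$total[i] <- sum(cc)
  }
  cbind(corTable, res)
}
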