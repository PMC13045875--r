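#' Round half away from zero
#'
#' Publication-style rounding: exact halves round away from zero (so 0.705
#' prints as 0.71), unlike [round()]'s round-half-even. A 1e-6 guard absorbs
#' binary representation error in values arriving at a half boundary.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-6) / p
}

twin_log <- function(fmt, ...) {
  if (isTRUE(getOption("twinDTI.verbose", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
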