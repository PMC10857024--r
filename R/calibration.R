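#' Total chlorophyll from extract absorbances (Arnon method)
#'
#' Computes total chlorophyll of an 80% acetone extract from its absorbance
#' at 645 nm and 663 nm as `20.2 * A645 + 8.02 * A663` (mg/L of extract).
#' Conversion to per-mass leaf content (extraction mass and volume scaling)
#' is the caller's concern.
#'
#' @param A645,A663 Nonnegative absorbances at 645 and 663 nm. Vectorised.
#' @return Total chlorophyll in mg/L of extract.
#' @examples
#' arnon_total_chlorophyll(1, 1)  # 28.22
#' @export
arnon_total_chlorophyll <- function(A645, A663) {
  if (any(!is.finite(A645)) || any(!is.finite(A663)) ||
      any(A645 < 0) || any(A663 < 0)) {
    stop("absorbances must be finite and nonnegative", call. = FALSE)
  }
  20.2 * A645 + 8.02 * A663
}

#' Linear calibration of wet-chemistry chlorophyll on SPAD readings
#'
#' Ordinary least squares of chemically determined chlorophyll on SPAD-502
#' readings, the standard check that meter readings track true chlorophyll.
#' For this univariate fit the coefficient of determination equals the
#' squared Pearson correlation, and the reported `r` carries the slope's
#' sign, so `r = sign(slope) * sqrt(R2)`.
#'
#' @param spad Numeric SPAD readings.
#' @param chem Numeric chemistry values (same length, n >= 3).
#' @return An object of class `calibration_fit` with fields `slope`,
#'   `intercept`, `R2`, `r`, `n`.
#' @export
fit_linear_calibration <- function(spad, chem) {
  if (length(spad) != length(chem)) {
    stop("spad and chem must have equal length", call. = FALSE)
  }
  if (length(spad) < 3) stop("calibration requires at least 3 pairs", call. = FALSE)
  if (stats::sd(spad) == 0 || stats::sd(chem) == 0) {
    stop("calibration requires nonzero variance in both variables", call. = FALSE)
  }
  fit <- stats::lm(chem ~ spad)
  slope <- unname(stats::coef(fit)[2])
  r <- stats::cor(spad, chem)
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         R2 = r^2,
         r = r,
         n = length(spad)),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> chem = %.4f * spad + %.4f  (R2 = %.3f, r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$R2, x$r, x$n))
  invisible(x)
}

#' Pearson r implied by a univariate R-squared and a slope sign
#'
#' For a simple linear regression, `R2 = r^2`; the correlation's magnitude is
#' therefore `sqrt(R2)`, signed like the slope. For example a positive-slope
#' calibration with `R2 = 0.95` has `r = 0.9747`, i.e. 0.975 to three
#' decimals.
#'
#' @param R2 Coefficient of determination in \[0, 1\].
#' @param slope_sign Sign of the fitted slope (+1 or -1).
#' @return The implied Pearson correlation coefficient.
#' @export
r_from_r2 <- function(R2, slope_sign = 1) {
  if (R2 < 0 || R2 > 1) stop("R2 must lie in [0, 1]", call. = FALSE)
  sign(slope_sign) * sqrt(R2)
}

#' Read a paired calibration table and write a fit report
#'
#' The paired table is delimited text with columns `sample_id`, `spad`,
#' `chem`. The fit report is a one-row CSV with `slope`, `intercept`, `R2`,
#' `r`, `n`.
#'
#' @param path Input CSV of pairs.
#' @return A [fit_linear_calibration()] result.
#' @export
calibrate_from_file <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("spad", "chem") %in% colnames(df))) {
    stop("calibration table needs 'spad' and 'chem' columns", call. = FALSE)
  }
  fit_linear_calibration(df$spad, df$chem)
}

#' @rdname calibrate_from_file
#' @param fit A `calibration_fit`.
#' @param out Output CSV path.
#' @export
write_calibration_report <- function(fit, out) {
  stopifnot(inherits(fit, "calibration_fit"))
  utils::write.csv(data.frame(slope = fit$slope, intercept = fit$intercept,
                              R2 = fit$R2, r = fit$r, n = fit$n),
                   out, row.names = FALSE)
  invisible(out)
}
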