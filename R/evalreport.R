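#' Root mean square error
#'
#' `RMSE = sqrt(mean((measured - predicted)^2))`, in the units of the
#' response (SPAD). Zero exactly when every prediction is exact.
#'
#' @param measured,predicted Numeric vectors of equal, nonzero length.
#' @return Nonnegative scalar.
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) == 0) {
    stop("measured and predicted must have equal, nonzero length", call. = FALSE)
  }
  sqrt(mean((measured - predicted)^2))
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - yp)^2) / sum((y - ym)^2)` where `ym` is the mean of
#' the measured values of the partition being scored (so the test partition
#' uses its own mean). At most 1; can be negative for predictors worse than
#' the mean; predicting the mean everywhere gives exactly 0.
#'
#' @param measured Numeric vector, length >= 2, not constant.
#' @param predicted Numeric vector of the same length.
#' @return Scalar <= 1.
#' @export
r_squared <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 2) {
    stop("measured and predicted must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) {
    stop("R2 undefined for constant measured values", call. = FALSE)
  }
  1 - sum((measured - predicted)^2) / ss_tot
}

#' Linear prediction form
#'
#' The dot product `sum(beta_i * H_i) + C`, the prediction equation of the
#' linear (PLSR) family applied to one feature vector.
#'
#' @param betas Numeric coefficients.
#' @param features Numeric feature values, same length as `betas`.
#' @param intercept Scalar constant `C`.
#' @return Predicted chlorophyll (SPAD units).
#' @export
linear_prediction <- function(betas, features, intercept = 0) {
  if (length(betas) != length(features)) {
    stop("betas and features must have equal length", call. = FALSE)
  }
  sum(betas * features) + intercept
}

#' Evaluation report for one fitted model on one feature set
#'
#' Bundles calibration- and prediction-partition metrics: `Rc2`/`RMSEc` on
#' the training data and `Rp2`/`RMSEp` on the held-out test data.
#'
#' @param feature_set Label of the feature set (an index name, `"all-svi"`,
#'   `"all-cvi"`, or `"fused"`).
#' @param family Model family label.
#' @param y_train,pred_train Measured and predicted responses, training
#'   partition.
#' @param y_test,pred_test Measured and predicted responses, test partition.
#' @return An object of class `model_report`.
#' @export
model_report <- function(feature_set, family, y_train, pred_train,
                         y_test, pred_test) {
  structure(
    list(feature_set = feature_set, family = family,
         Rc2 = r_squared(y_train, pred_train),
         RMSEc = rmse(y_train, pred_train),
         Rp2 = r_squared(y_test, pred_test),
         RMSEp = rmse(y_test, pred_test),
         n_train = length(y_train), n_test = length(y_test)),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s / %s: Rc2=%.3f RMSEc=%.2f | Rp2=%.3f RMSEp=%.2f (n=%d/%d)\n",
              x$feature_set, x$family, x$Rc2, x$RMSEc, x$Rp2, x$RMSEp,
              x$n_train, x$n_test))
  invisible(x)
}

#' Assemble model reports into a wide comparison table
#'
#' One row per feature set, with paired `<family>_Rp2` / `<family>_RMSEp`
#' columns per model family — the layout used to compare an automated
#' search winner against baseline regressors across per-index and combined
#' feature sets. Duplicate (feature_set, family) pairs are an aggregation
#' error.
#'
#' @param results List of [model_report()] objects (>= 1).
#' @return Data frame, one row per feature set.
#' @export
experiment_report <- function(results) {
  if (length(results) == 0) stop("no results to report", call. = FALSE)
  if (inherits(results, "model_report")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "model_report")))
  keys <- vapply(results, function(r) paste(r$feature_set, r$family, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    stop(sprintf("duplicate report for feature set '%s', family '%s'",
                 sub("\r.*", "", dup), sub(".*\r", "", dup)), call. = FALSE)
  }
  fsets <- unique(vapply(results, `[[`, character(1), "feature_set"))
  fams <- unique(vapply(results, `[[`, character(1), "family"))
  out <- data.frame(feature_set = fsets, stringsAsFactors = FALSE)
  for (fam in fams) {
    out[[paste0(fam, "_Rp2")]] <- NA_real_
    out[[paste0(fam, "_RMSEp")]] <- NA_real_
  }
  for (r in results) {
    i <- match(r$feature_set, fsets)
    out[i, paste0(r$family, "_Rp2")] <- r$Rp2
    out[i, paste0(r$family, "_RMSEp")] <- r$RMSEp
  }
  out
}

#' Write an experiment report table; plot measured vs predicted values
#'
#' @param report Data frame from [experiment_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_experiment_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_experiment_report
#' @param measured,predicted Held-out measured and predicted SPAD values.
#' @param title Plot title (e.g. feature set and family).
#' @export
plot_predictions <- function(measured, predicted, path, title = "") {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  lim <- range(c(measured, predicted))
  plot(measured, predicted, xlim = lim, ylim = lim,
       xlab = "Measured chlorophyll (SPAD)",
       ylab = "Predicted chlorophyll (SPAD)",
       main = title, pch = 19, col = grDevices::rgb(0, 0.4, 0, 0.5))
  graphics::abline(0, 1, lty = 2)
  leg <- sprintf("Rp2 = %.3f, RMSEp = %.2f",
                 r_squared(measured, predicted), rmse(measured, predicted))
  graphics::legend("topleft", legend = leg, bty = "n")
  invisible(path)
}
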