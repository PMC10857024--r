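#' Construct a leaf reflectance spectrum
#'
#' A spectrum is a pair of aligned numeric vectors: a strictly increasing
#' wavelength grid in nanometres and the reflectance measured at each
#' wavelength. Raw reflectance is a unitless fraction in \[0, 1\];
#' preprocessed spectra (e.g. after [snv()]) may take any sign, which the
#' `preprocessed` flag records.
#'
#' @param wavelengths Numeric vector of wavelengths (nm), strictly increasing.
#' @param reflectance Numeric vector of reflectance values, same length.
#' @param preprocessed Logical; if `TRUE` the \[0, 1\] range check is skipped.
#' @return An object of class `leaf_spectrum`.
#' @examples
#' s <- leaf_spectrum(c(500, 600, 700), c(0.1, 0.4, 0.2))
#' band_value(s, 650)
#' @export
leaf_spectrum <- function(wavelengths, reflectance, preprocessed = FALSE) {
  if (!is.numeric(wavelengths) || !is.numeric(reflectance)) {
    stop("wavelengths and reflectance must be numeric", call. = FALSE)
  }
  if (length(wavelengths) != length(reflectance)) {
    stop("wavelengths and reflectance must have equal length", call. = FALSE)
  }
  if (anyNA(wavelengths) || anyNA(reflectance)) {
    stop("spectrum must not contain missing values", call. = FALSE)
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!preprocessed && (min(reflectance) < 0 || max(reflectance) > 1)) {
    stop("raw reflectance must lie in [0, 1]; set preprocessed = TRUE for transformed spectra",
         call. = FALSE)
  }
  structure(
    list(wavelengths = as.numeric(wavelengths),
         reflectance = as.numeric(reflectance),
         preprocessed = isTRUE(preprocessed)),
    class = "leaf_spectrum"
  )
}

#' @export
print.leaf_spectrum <- function(x, ...) {
  cat(sprintf("<leaf_spectrum> %d bands, %.0f-%.0f nm%s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              if (x$preprocessed) " (preprocessed)" else ""))
  invisible(x)
}

#' Reflectance at a target wavelength
#'
#' Looks up reflectance on the instrument grid. An exact grid hit returns the
#' stored value; otherwise the value is linearly interpolated between the two
#' bracketing grid points. Interpolation (rather than nearest-neighbour) is
#' used because field spectroradiometer resolution is coarser in the
#' short-wave infrared than in the visible, so index wavelengths need not
#' coincide with grid points.
#'
#' @param spectrum A [leaf_spectrum()].
#' @param target_nm Wavelength(s) in nm, each within the grid range.
#' @return Numeric reflectance value(s).
#' @export
band_value <- function(spectrum, target_nm) {
  stopifnot(inherits(spectrum, "leaf_spectrum"))
  w <- spectrum$wavelengths
  if (any(target_nm < w[1] | target_nm > w[length(w)])) {
    stop(sprintf("target wavelength outside spectral range [%g, %g] nm",
                 w[1], w[length(w)]), call. = FALSE)
  }
  stats::approx(w, spectrum$reflectance, xout = target_nm, method = "linear")$y
}

#' Standard normal variate (SNV) transform
#'
#' Centres and scales each spectrum to zero mean and unit standard deviation
#' (sample standard deviation, n - 1 denominator). SNV removes per-sample
#' multiplicative and additive scatter: two spectra differing only by an
#' affine map `a * x + b` (a > 0) have identical SNV transforms.
#'
#' @param spectrum A [leaf_spectrum()] with at least 2 bands and nonzero spread.
#' @return A preprocessed `leaf_spectrum`.
#' @export
snv <- function(spectrum) {
  stopifnot(inherits(spectrum, "leaf_spectrum"))
  x <- spectrum$reflectance
  if (length(x) < 2) stop("SNV requires at least 2 bands", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("SNV undefined for a constant spectrum (zero variance)", call. = FALSE)
  leaf_spectrum(spectrum$wavelengths, (x - mean(x)) / s, preprocessed = TRUE)
}

# Savitzky-Golay convolution weights for interior points: value at the centre
# of a local least-squares polynomial fit of degree `polyorder` over `window`
# equally spaced points. Derived from the normal equations, not tabulated.
sg_weights <- function(window, polyorder) {
  half <- (window - 1L) / 2L
  z <- (-half):half
  X <- outer(z, 0:polyorder, `^`)
  # first row of (X'X)^{-1} X' = fitted value at z = 0
  H <- solve(crossprod(X), t(X))
  H[1L, ]
}

#' Savitzky-Golay smoothing
#'
#' Replaces each reflectance value with the centre of a local least-squares
#' polynomial fit of order `polyorder` over a `window`-point neighbourhood.
#' Requires a uniformly spaced wavelength grid. Edge points are smoothed by
#' fitting the polynomial on the one-sided truncated window (no padding), so
#' the output has the same length as the input. Exactly reproduces any signal
#' that is a polynomial of degree at most `polyorder`.
#'
#' @param spectrum A [leaf_spectrum()] on a uniform grid.
#' @param window Odd integer window length, greater than `polyorder`.
#' @param polyorder Polynomial order of the local fit.
#' @return A smoothed `leaf_spectrum` (flagged preprocessed, since smoothing
#'   of preprocessed inputs can leave any range).
#' @export
savitzky_golay <- function(spectrum, window = 11L, polyorder = 2L) {
  stopifnot(inherits(spectrum, "leaf_spectrum"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window <= polyorder) stop("window must exceed polyorder", call. = FALSE)
  w <- spectrum$wavelengths
  if (length(w) < window) stop("spectrum shorter than window", call. = FALSE)
  dw <- diff(w)
  if (max(dw) - min(dw) > 1e-8 * mean(dw)) {
    stop("savitzky_golay requires a uniform wavelength grid; resample first",
         call. = FALSE)
  }
  x <- spectrum$reflectance
  n <- length(x)
  half <- (window - 1L) / 2L
  out <- as.numeric(stats::filter(x, sg_weights(window, polyorder), sides = 2))
  # one-sided truncated-window polynomial fits at the edges
  for (i in c(seq_len(half), (n - half + 1L):n)) {
    idx <- max(1L, i - half):min(n, i + half)
    z <- w[idx] - w[i]
    X <- outer(z, 0:polyorder, `^`)
    beta <- solve(crossprod(X), crossprod(X, x[idx]))
    out[i] <- beta[1L]
  }
  leaf_spectrum(w, out, preprocessed = TRUE)
}

#' Spectral dataset: samples on a shared wavelength grid with SPAD responses
#'
#' @param ids Character or integer sample identifiers (unique).
#' @param wavelengths Shared wavelength grid (nm), strictly increasing.
#' @param reflectance Numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param spad Numeric SPAD reading per sample (the response variable).
#' @param preprocessed Logical; whether reflectance has been transformed.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(ids, wavelengths, reflectance, spad,
                             preprocessed = FALSE) {
  reflectance <- as.matrix(reflectance)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  if (nrow(reflectance) != length(ids)) {
    stop("one reflectance row per sample id required", call. = FALSE)
  }
  if (ncol(reflectance) != length(wavelengths)) {
    stop("one reflectance column per wavelength required", call. = FALSE)
  }
  if (length(spad) != length(ids)) {
    stop("one SPAD response per sample required", call. = FALSE)
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!preprocessed && (min(reflectance) < 0 || max(reflectance) > 1)) {
    stop("raw reflectance must lie in [0, 1]", call. = FALSE)
  }
  dimnames(reflectance) <- list(ids, as.character(wavelengths))
  structure(
    list(ids = ids, wavelengths = as.numeric(wavelengths),
         reflectance = reflectance, spad = as.numeric(spad),
         preprocessed = isTRUE(preprocessed)),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d bands (%.0f-%.0f nm)\n",
              length(x$ids), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Extract one sample of a spectral dataset as a spectrum
#' @param dataset A [spectral_dataset()].
#' @param i Row index or sample id.
#' @return A [leaf_spectrum()].
#' @export
get_spectrum <- function(dataset, i) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (is.character(i)) i <- match(i, dataset$ids)
  leaf_spectrum(dataset$wavelengths, dataset$reflectance[i, ],
                preprocessed = dataset$preprocessed)
}

#' Apply Savitzky-Golay smoothing and SNV to every spectrum in a dataset
#'
#' The conventional chemometric order is applied: smoothing first, then
#' per-spectrum standardisation, so that SNV normalises the smoothed signal.
#' Either step can be disabled.
#'
#' @param dataset A [spectral_dataset()].
#' @param sg Logical; apply Savitzky-Golay smoothing.
#' @param window,polyorder Savitzky-Golay parameters (see [savitzky_golay()]).
#' @param do_snv Logical; apply the SNV transform after smoothing.
#' @return A preprocessed `spectral_dataset`.
#' @export
preprocess_dataset <- function(dataset, sg = TRUE, window = 11L, polyorder = 2L,
                               do_snv = TRUE) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  refl <- dataset$reflectance
  out <- t(apply(refl, 1L, function(row) {
    s <- leaf_spectrum(dataset$wavelengths, row,
                       preprocessed = dataset$preprocessed)
    if (sg) s <- savitzky_golay(s, window, polyorder)
    if (do_snv) s <- snv(s)
    s$reflectance
  }))
  spectral_dataset(dataset$ids, dataset$wavelengths, out, dataset$spad,
                   preprocessed = TRUE)
}

#' Write / read a wide spectra table
#'
#' The on-disk format is comma-separated text: a header row of
#' `sample_id` followed by the numeric wavelengths in nm, then one row per
#' sample. A paired responses file (written by [write_responses_table()])
#' carries the SPAD values.
#'
#' @param dataset A [spectral_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  df <- data.frame(sample_id = dataset$ids,
                   dataset$reflectance, check.names = FALSE)
  colnames(df) <- c("sample_id", as.character(dataset$wavelengths))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_table
#' @param spad Optional SPAD responses to attach on read (default all `NA`;
#'   use [read_responses_table()] to recover them from the responses file).
#' @param preprocessed Logical; when `FALSE` (raw mode) values outside
#'   \[0, 1\] are a format error.
#' @export
read_spectra_table <- function(path, spad = NULL, preprocessed = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2 || colnames(df)[1] != "sample_id") {
    stop("spectra table must start with a 'sample_id' column", call. = FALSE)
  }
  wl <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (anyNA(wl)) {
    bad <- which(is.na(wl))[1] + 1L
    stop(sprintf("non-numeric wavelength in header column %d", bad), call. = FALSE)
  }
  if (length(wl) > 1 && any(diff(wl) <= 0)) {
    stop("header wavelengths must be strictly increasing", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    num <- suppressWarnings(
      matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])), nrow = nrow(df)))
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric reflectance cell at row %d, column %d",
                 bad[1, 1], bad[1, 2] + 1L), call. = FALSE)
  }
  if (!preprocessed && (min(m) < 0 || max(m) > 1)) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    stop(sprintf("reflectance outside [0, 1] at row %d, column %d (value %g)",
                 bad[1, 1], bad[1, 2] + 1L, m[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  }
  if (is.null(spad)) spad <- rep(NA_real_, nrow(m))
  spectral_dataset(df$sample_id, wl, m, spad, preprocessed = preprocessed)
}

#' Write / read the responses table (sample_id, true_chl, spad)
#' @param ids Sample ids.
#' @param spad SPAD readings.
#' @param true_chl Optional true chlorophyll values (synthetic data only).
#' @param path CSV path.
#' @return `path` invisibly, or for the reader a data frame.
#' @export
write_responses_table <- function(ids, spad, true_chl = NULL, path) {
  df <- data.frame(sample_id = as.character(ids),
                   true_chl = if (is.null(true_chl)) NA_real_ else true_chl,
                   spad = spad)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses_table
#' @export
read_responses_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Random 70/30-style train/test split
#'
#' Partitions sample indices by a seeded random shuffle. The training size is
#' `round(n * train_fraction)` with exact halves rounded up, so 3600 samples
#' at 0.7 give the conventional 2520/1080 split.
#'
#' @param n Number of samples (or an object with `ids` to split).
#' @param train_fraction Proportion of samples assigned to training, in (0, 1).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
train_test_split <- function(n, train_fraction = 0.7, seed = 1L) {
  if (inherits(n, "spectral_dataset") || is.list(n)) n <- length(n$ids)
  n <- as.integer(n)
  if (n < 2) stop("need at least 2 samples to split", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_train <- as.integer(floor(n * train_fraction + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}
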