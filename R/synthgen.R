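#' Configuration for the synthetic leaf-data generator
#'
#' The generator emulates the statistical structure a field spectrometer /
#' SPAD-meter / RGB-camera campaign produces, so that every downstream stage
#' of the pipeline can be exercised without measured data. A leaf spectrum is
#' modelled as a smooth baseline (moderate visible reflectance rising to a
#' near-infrared plateau) attenuated by Gaussian chlorophyll absorption bands
#' in the blue and red, combined multiplicatively so reflectance never
#' saturates to zero, with band depth increasing in true chlorophyll as
#' `depth * chl / (chl + sat_k)`, plus fixed-depth water bands in the
#' short-wave infrared. Per-sample multiplicative/additive scatter (removable
#' by SNV) is applied before additive instrument noise, and the result is
#' clipped to \[0, 1\]. SPAD readings follow a linear observation model on
#' true chlorophyll.
#'
#' @param wavelength_grid Wavelength grid in nm (default 350-2500 at 1 nm).
#' @param chl_range Range of true chlorophyll in SPAD-equivalent units.
#' @param absorber_bands Matrix-like list of chlorophyll absorbers; each row
#'   `c(center_nm, width_nm, max_depth)` with `max_depth` in \[0, 1).
#' @param sat_k Half-saturation constant of the absorber depth response.
#' @param water_bands Rows `c(center_nm, width_nm, depth)` of fixed absorbers.
#' @param baseline_visible,baseline_nir Baseline reflectance levels either
#'   side of the red edge.
#' @param red_edge_nm,red_edge_width Centre and scale (nm) of the logistic
#'   baseline transition.
#' @param scatter_sd_mult,scatter_sd_add Standard deviations of the
#'   per-sample multiplicative (around 1) and additive (around 0) scatter.
#' @param noise_sd Additive per-band reflectance noise standard deviation.
#' @param spad_slope,spad_intercept,spad_noise_sd SPAD observation model:
#'   `spad = slope * chl + intercept + N(0, sd)`.
#' @param camera_noise_sd Per-sample, per-channel noise (8-bit counts) of the
#'   camera observation model: shot-to-shot exposure and illumination
#'   variation that affects the RGB record of a plant but not its
#'   spectrometer reading.
#' @param image_size Side length (pixels) of rendered leaf images.
#' @param image_noise_sd Per-pixel, per-channel noise (8-bit counts) of
#'   rendered images.
#' @param background_rgb Background colour of rendered images (soil brown).
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(wavelength_grid = 350:2500,
                             chl_range = c(5, 60),
                             absorber_bands = rbind(
                               c(430, 40, 0.85),
                               c(460, 40, 0.75),
                               c(640, 45, 0.80),
                               c(665, 30, 0.90)),
                             sat_k = 25,
                             water_bands = rbind(
                               c(1450, 80, 0.55),
                               c(1940, 90, 0.65)),
                             baseline_visible = 0.50,
                             baseline_nir = 0.55,
                             red_edge_nm = 705,
                             red_edge_width = 18,
                             scatter_sd_mult = 0.04,
                             scatter_sd_add = 0.008,
                             noise_sd = 0.004,
                             spad_slope = 1.0,
                             spad_intercept = 0.0,
                             spad_noise_sd = 1.2,
                             camera_noise_sd = 6,
                             image_size = 96L,
                             image_noise_sd = 8,
                             background_rgb = c(115, 85, 58),
                             seed = 1L) {
  cfg <- list(wavelength_grid = as.numeric(wavelength_grid),
              chl_range = as.numeric(chl_range),
              absorber_bands = as.matrix(absorber_bands),
              sat_k = sat_k,
              water_bands = as.matrix(water_bands),
              baseline_visible = baseline_visible,
              baseline_nir = baseline_nir,
              red_edge_nm = red_edge_nm,
              red_edge_width = red_edge_width,
              scatter_sd_mult = scatter_sd_mult,
              scatter_sd_add = scatter_sd_add,
              noise_sd = noise_sd,
              spad_slope = spad_slope,
              spad_intercept = spad_intercept,
              spad_noise_sd = spad_noise_sd,
              camera_noise_sd = camera_noise_sd,
              image_size = as.integer(image_size),
              image_noise_sd = image_noise_sd,
              background_rgb = as.numeric(background_rgb),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  w <- cfg$wavelength_grid
  if (any(diff(w) <= 0)) stop("wavelength_grid must be strictly increasing", call. = FALSE)
  if (w[1] > 350 || w[length(w)] < 2500) {
    stop("wavelength_grid must cover 350-2500 nm", call. = FALSE)
  }
  if (cfg$chl_range[1] >= cfg$chl_range[2]) {
    stop("chl_range must be an increasing pair", call. = FALSE)
  }
  depths <- cfg$absorber_bands[, 3]
  if (any(depths < 0 | depths >= 1)) {
    stop("absorber max_depth values must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$spad_noise_sd < 0 || cfg$camera_noise_sd < 0) {
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic noiseless part of the reflectance model.
spectrum_mean <- function(chl, cfg) {
  w <- cfg$wavelength_grid
  base <- cfg$baseline_visible +
    (cfg$baseline_nir - cfg$baseline_visible) /
      (1 + exp(-(w - cfg$red_edge_nm) / cfg$red_edge_width))
  sat <- chl / (chl + cfg$sat_k)
  # absorbers combine multiplicatively (Beer-Lambert-like), so reflectance
  # decreases strictly with chl but never saturates to zero
  trans <- rep(1, length(w))
  for (i in seq_len(nrow(cfg$absorber_bands))) {
    b <- cfg$absorber_bands[i, ]
    trans <- trans * (1 - b[3] * sat * exp(-(w - b[1])^2 / (2 * b[2]^2)))
  }
  for (i in seq_len(nrow(cfg$water_bands))) {
    b <- cfg$water_bands[i, ]
    trans <- trans * (1 - b[3] * exp(-(w - b[1])^2 / (2 * b[2]^2)))
  }
  pmax(0, pmin(1, base * trans))
}

#' Generate one synthetic leaf reflectance spectrum
#'
#' Draws scatter and noise from the current RNG stream; call `set.seed()`
#' first (or use [generate_dataset()], which seeds from its config) for
#' reproducibility. At zero noise the model is deterministic in `chl`:
#' green (~559 nm) and red (~665 nm) reflectance decrease strictly with
#' chlorophyll while the NIR plateau is unaffected, which is the contrast
#' that chlorophyll-sensitive ratio indices exploit.
#'
#' @param chl True chlorophyll (SPAD-equivalent units), within
#'   `config$chl_range`.
#' @param config A [generator_config()].
#' @return A [leaf_spectrum()] on the configured grid.
#' @export
generate_spectrum <- function(chl, config = generator_config()) {
  validate_generator_config(config)
  if (chl < config$chl_range[1] || chl > config$chl_range[2]) {
    stop(sprintf("chl = %g outside chl_range [%g, %g]", chl,
                 config$chl_range[1], config$chl_range[2]), call. = FALSE)
  }
  mu <- spectrum_mean(chl, config)
  a <- 1 + stats::rnorm(1, 0, config$scatter_sd_mult)
  b <- stats::rnorm(1, 0, config$scatter_sd_add)
  r <- a * mu + b + stats::rnorm(length(mu), 0, config$noise_sd)
  leaf_spectrum(config$wavelength_grid, pmax(0, pmin(1, r)))
}

#' Generate a full synthetic leaf dataset
#'
#' Draws `n` true chlorophyll values uniformly over the configured range,
#' simulates a reflectance spectrum, a SPAD reading and an RGB colour sample
#' for each, and returns them as a `leaf_dataset`. The result is a pure
#' function of `(config, config$seed)`: identical configurations give
#' bit-identical datasets.
#'
#' @param n Number of samples (>= 1).
#' @param config A [generator_config()].
#' @return A list of class `leaf_dataset` with elements `ids`, `wavelengths`,
#'   `reflectance` (n x bands matrix), `true_chl`, `spad`, and `rgb`
#'   (a data frame of [color_sample()] channels).
#' @export
generate_dataset <- function(n, config = generator_config()) {
  validate_generator_config(config)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer", call. = FALSE)
  set.seed(config$seed)
  chl <- stats::runif(n, config$chl_range[1], config$chl_range[2])
  refl <- matrix(NA_real_, n, length(config$wavelength_grid))
  for (i in seq_len(n)) {
    refl[i, ] <- generate_spectrum(chl[i], config)$reflectance
  }
  spad <- config$spad_slope * chl + config$spad_intercept +
    stats::rnorm(n, 0, config$spad_noise_sd)
  rgb <- do.call(rbind, lapply(seq_len(n), function(i) {
    cs <- spectrum_to_rgb(leaf_spectrum(config$wavelength_grid, refl[i, ]))
    if (config$camera_noise_sd > 0) {
      ch <- c(cs$R, cs$G, cs$B) + stats::rnorm(3, 0, config$camera_noise_sd)
      ch <- pmax(0, pmin(255, round(ch)))
      cs <- color_sample(ch[1], ch[2], ch[3])
    }
    as.data.frame(cs[c("R", "G", "B", "rn", "gn", "bn")])
  }))
  ids <- sprintf("s%04d", seq_len(n))
  rownames(rgb) <- ids
  structure(
    list(ids = ids, wavelengths = config$wavelength_grid, reflectance = refl,
         true_chl = chl, spad = spad, rgb = rgb, config = config),
    class = "leaf_dataset"
  )
}

#' @export
print.leaf_dataset <- function(x, ...) {
  cat(sprintf("<leaf_dataset> %d samples, %d bands, chl %.1f-%.1f\n",
              length(x$ids), length(x$wavelengths),
              min(x$true_chl), max(x$true_chl)))
  invisible(x)
}

#' Coerce a leaf_dataset to a spectral_dataset (spectra + SPAD responses)
#' @param dataset A `leaf_dataset` from [generate_dataset()].
#' @return A [spectral_dataset()].
#' @export
as_spectral_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "leaf_dataset"))
  spectral_dataset(dataset$ids, dataset$wavelengths, dataset$reflectance,
                   dataset$spad)
}

#' Integrate a spectrum into an RGB colour sample
#'
#' The camera model is a boxcar response per channel: each 8-bit channel is
#' `round(255 * mean reflectance)` over its wavelength interval, clipped to
#' \[0, 255\]. Normalised channels `rn = R / (R + G + B)` etc. are computed
#' from the channel values.
#'
#' @param spectrum A [leaf_spectrum()].
#' @param band_defs Named list of `c(lo, hi)` nm intervals for `B`, `G`, `R`.
#' @return A [color_sample()].
#' @export
spectrum_to_rgb <- function(spectrum,
                            band_defs = list(B = c(450, 495),
                                             G = c(495, 570),
                                             R = c(620, 700))) {
  stopifnot(inherits(spectrum, "leaf_spectrum"))
  w <- spectrum$wavelengths
  chan <- vapply(band_defs, function(b) {
    if (b[1] < w[1] || b[2] > w[length(w)]) {
      stop(sprintf("channel band [%g, %g] outside spectral range", b[1], b[2]),
           call. = FALSE)
    }
    sel <- w >= b[1] & w <= b[2]
    mean(spectrum$reflectance[sel])
  }, numeric(1))
  to8 <- function(x) max(0, min(255, round(255 * x)))
  color_sample(R = to8(chan[["R"]]), G = to8(chan[["G"]]), B = to8(chan[["B"]]))
}

#' Render a synthetic leaf image with its ground-truth mask
#'
#' Draws an elliptical leaf filled with the sample colour (plus per-pixel
#' Gaussian noise) on a uniformly coloured background (default soil brown,
#' also noised). Ellipse axes are drawn so the leaf occupies 20-60% of the
#' frame. Used as a verifiable fixture for the segmentation stage.
#'
#' @param color A [color_sample()] giving the leaf fill colour.
#' @param config A [generator_config()] (image size, noise, background).
#' @param seed Integer seed for the leaf geometry and pixel noise.
#' @return List with `image` (size x size x 3 array of 8-bit values) and
#'   `mask` (logical matrix marking leaf pixels).
#' @export
render_leaf_image <- function(color, config = generator_config(), seed = 1L) {
  stopifnot(inherits(color, "color_sample"))
  set.seed(seed)
  sz <- config$image_size
  # sample semi-axes until the ellipse area fraction pi*a*b/sz^2 is in [0.2, 0.6]
  repeat {
    ax <- stats::runif(1, 0.25, 0.45) * sz
    bx <- stats::runif(1, 0.25, 0.45) * sz
    frac <- pi * ax * bx / sz^2
    if (frac >= 0.2 && frac <= 0.6) break
  }
  cx <- sz / 2 + stats::runif(1, -0.05, 0.05) * sz
  cy <- sz / 2 + stats::runif(1, -0.05, 0.05) * sz
  xs <- matrix(rep(seq_len(sz), each = sz), sz, sz)   # column index
  ys <- matrix(rep(seq_len(sz), times = sz), sz, sz)  # row index
  mask <- ((xs - cx) / ax)^2 + ((ys - cy) / bx)^2 <= 1
  img <- array(0, dim = c(sz, sz, 3))
  leaf <- c(color$R, color$G, color$B)
  for (k in 1:3) {
    plane <- matrix(config$background_rgb[k], sz, sz)
    plane[mask] <- leaf[k]
    if (config$image_noise_sd > 0) {
      plane <- plane + matrix(stats::rnorm(sz * sz, 0, config$image_noise_sd), sz, sz)
    }
    img[, , k] <- pmax(0, pmin(255, round(plane)))
  }
  list(image = img, mask = mask)
}

#' Invert the Arnon equation: absorbance pair for a target total chlorophyll
#'
#' Returns a nonnegative `(A645, A663)` pair satisfying
#' `20.2 * A645 + 8.02 * A663 = total_chl` exactly, for round-trip testing of
#' [arnon_total_chlorophyll()]. The fraction of the total carried by the
#' A645 term is `split` (randomised by default).
#'
#' @param total_chl Target total chlorophyll (mg/L of extract), >= 0.
#' @param split Proportion in \[0, 1\] of `total_chl` attributed to the
#'   `20.2 * A645` term; `NULL` draws it uniformly.
#' @return Named numeric vector `c(A645 = ..., A663 = ...)`.
#' @export
generate_absorbance_pair <- function(total_chl, split = NULL) {
  if (!is.numeric(total_chl) || total_chl < 0) {
    stop("total_chl must be nonnegative", call. = FALSE)
  }
  if (is.null(split)) split <- stats::runif(1)
  if (split < 0 || split > 1) stop("split must lie in [0, 1]", call. = FALSE)
  c(A645 = split * total_chl / 20.2,
    A663 = (1 - split) * total_chl / 8.02)
}

#' Write a generated dataset to an output directory
#'
#' Produces the plain-text artifacts of a simulation run: `spectra.csv`
#' (wide table, header = wavelengths), `responses.csv`
#' (`sample_id`, `true_chl`, `spad`), `colors.csv` (RGB channel table), and
#' optionally paired `images/<id>.png` + `masks/<id>.png` renders.
#'
#' @param dataset A `leaf_dataset`.
#' @param dir Output directory (created if absent).
#' @param images Number of leaf images to render (0 for none).
#' @return `dir`, invisibly.
#' @export
write_leaf_dataset <- function(dataset, dir, images = 0L) {
  stopifnot(inherits(dataset, "leaf_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra_table(as_spectral_dataset(dataset), file.path(dir, "spectra.csv"))
  write_responses_table(dataset$ids, dataset$spad, dataset$true_chl,
                        file.path(dir, "responses.csv"))
  utils::write.csv(cbind(sample_id = dataset$ids, dataset$rgb),
                   file.path(dir, "colors.csv"), row.names = FALSE)
  images <- min(as.integer(images), length(dataset$ids))
  if (images > 0) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (i in seq_len(images)) {
      cs <- color_sample(dataset$rgb$R[i], dataset$rgb$G[i], dataset$rgb$B[i])
      ren <- render_leaf_image(cs, dataset$config,
                               seed = dataset$config$seed + i)
      png::writePNG(ren$image / 255,
                    file.path(dir, "images", paste0(dataset$ids[i], ".png")))
      png::writePNG(ren$mask * 1,
                    file.path(dir, "masks", paste0(dataset$ids[i], ".png")))
    }
  }
  invisible(dir)
}

#' Read a generator configuration from a plain-text key:value file
#'
#' Lines have the form `key: value`; vector values are comma-separated;
#' blank lines and lines starting with `#` are ignored. Unknown keys are an
#' error. Keys absent from the file keep their [generator_config()] defaults.
#'
#' @param path Path to the config file.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  scalar_keys <- c("sat_k", "baseline_visible", "baseline_nir", "red_edge_nm",
                   "red_edge_width", "scatter_sd_mult", "scatter_sd_add",
                   "noise_sd", "spad_slope", "spad_intercept", "spad_noise_sd",
                   "camera_noise_sd", "image_size", "image_noise_sd", "seed")
  vector_keys <- c("wavelength_grid", "chl_range", "background_rgb")
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key %in% scalar_keys) {
      args[[key]] <- as.numeric(val)
    } else if (key %in% vector_keys) {
      v <- as.numeric(strsplit(val, ",")[[1]])
      if (key == "wavelength_grid" && length(v) == 2) v <- v[1]:v[2]
      args[[key]] <- v
    } else {
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    }
  }
  do.call(generator_config, args)
}
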