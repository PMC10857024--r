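test_that("zero chlorophyll leaves the red band at the baseline", {
  cfg <- noiseless_config(chl_range = c(0, 60))
  s <- generate_spectrum(0, cfg)
  expect_equal(band_value(s, 665), expected_baseline(cfg, 665), tolerance = 1e-10)
})

test_that("green and red reflectance decrease strictly with chlorophyll at zero noise", {
  cfg <- noiseless_config()
  chls <- seq(5, 60, length.out = 50)
  r559 <- vapply(chls, function(c) band_value(generate_spectrum(c, cfg), 559), numeric(1))
  r665 <- vapply(chls, function(c) band_value(generate_spectrum(c, cfg), 665), numeric(1))
  expect_true(all(diff(r559) < 0))
  expect_true(all(diff(r665) < 0))
})

test_that("generated reflectance is always clipped to [0, 1]", {
  cfg <- generator_config(noise_sd = 0.2, scatter_sd_add = 0.2, seed = 7)
  set.seed(7)
  for (chl in c(5, 30, 60)) {
    s <- generate_spectrum(chl, cfg)
    expect_gte(min(s$reflectance), 0)
    expect_lte(max(s$reflectance), 1)
  }
})

test_that("chlorophyll outside the configured range is rejected", {
  cfg <- generator_config()
  expect_error(generate_spectrum(4.9, cfg), "chl_range")
  expect_error(generate_spectrum(61, cfg), "chl_range")
})

test_that("identical seeds give bit-identical datasets", {
  a <- generate_dataset(100, generator_config(seed = 1))
  b <- generate_dataset(100, generator_config(seed = 1))
  expect_identical(a$reflectance, b$reflectance)
  expect_identical(a$spad, b$spad)
  expect_identical(a$rgb, b$rgb)
  c <- generate_dataset(100, generator_config(seed = 2))
  expect_false(identical(a$spad, c$spad))
})

test_that("the SPAD observation model is recovered by least squares", {
  cfg <- generator_config(spad_slope = 1.0, spad_intercept = 0,
                          spad_noise_sd = 0.3, seed = 42)
  ds <- generate_dataset(1000, cfg)
  fit <- stats::lm(ds$spad ~ ds$true_chl)
  expect_lt(abs(stats::coef(fit)[2] - cfg$spad_slope) / cfg$spad_slope, 0.02)
})

test_that("dataset generation rejects non-positive sample counts", {
  expect_error(generate_dataset(0, generator_config()), "positive")
})

test_that("the camera model maps flat spectra to equal channels", {
  wl <- 350:2500
  flat <- leaf_spectrum(wl, rep(0.5, length(wl)))
  cs <- spectrum_to_rgb(flat)
  expect_equal(c(cs$R, cs$G, cs$B), c(128, 128, 128))
  dark <- leaf_spectrum(wl, rep(0, length(wl)))
  cs0 <- spectrum_to_rgb(dark)
  expect_equal(c(cs0$R, cs0$G, cs0$B), c(0, 0, 0))
})

test_that("high-chlorophyll leaves look green to the camera", {
  cfg <- noiseless_config()
  for (chl in c(40, 50, 60)) {
    cs <- spectrum_to_rgb(generate_spectrum(chl, cfg))
    expect_gt(cs$G, cs$R)
    expect_gt(cs$G, cs$B)
  }
})

test_that("camera bands outside the spectral range are rejected", {
  s <- leaf_spectrum(seq(500, 600, by = 5), runif(21, 0.2, 0.4))
  expect_error(spectrum_to_rgb(s), "outside")
})

test_that("leaf renders honour colour, area and determinism contracts", {
  cfg <- noiseless_config(image_noise_sd = 0)
  cs <- color_sample(40, 160, 30)
  ren <- render_leaf_image(cs, cfg, seed = 3)
  means <- vapply(1:3, function(k) mean(ren$image[, , k][ren$mask]), numeric(1))
  expect_equal(means, c(40, 160, 30))
  for (seed in 1:5) {
    r <- render_leaf_image(cs, cfg, seed = seed)
    frac <- mean(r$mask)
    expect_gte(frac, 0.2)
    expect_lte(frac, 0.6)
  }
  again <- render_leaf_image(cs, cfg, seed = 3)
  expect_identical(ren$image, again$image)
  expect_identical(ren$mask, again$mask)
})

test_that("absorbance pairs invert the total-chlorophyll equation", {
  expect_equal(unname(generate_absorbance_pair(0)), c(0, 0))
  set.seed(1)
  for (total in runif(20, 0, 80)) {
    p <- generate_absorbance_pair(total)
    expect_gte(min(p), 0)
    expect_equal(arnon_total_chlorophyll(p[["A645"]], p[["A663"]]), total,
                 tolerance = 1e-9)
  }
  # forcing equal absorbances: 20.2 a + 8.02 a = 28.22 has solution a = 1
  p <- generate_absorbance_pair(28.22, split = 20.2 / (20.2 + 8.02))
  expect_equal(unname(p), c(1, 1), tolerance = 1e-12)
  expect_error(generate_absorbance_pair(-1), "nonnegative")
})

test_that("chlorophyll-sensitive ratio indices increase strictly with chlorophyll", {
  cfg <- noiseless_config()
  chls <- seq(5, 60, length.out = 50)
  for (idx in c("GRVI", "CIgreen", "NDVI")) {
    vals <- vapply(chls, function(c) compute_svi(generate_spectrum(c, cfg), idx),
                   numeric(1))
    expect_true(all(diff(vals) > 0), label = paste(idx, "strictly increasing"))
  }
})

test_that("generator configs round-trip through the key:value file format", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# generator settings",
               "chl_range: 10, 50",
               "noise_sd: 0.002",
               "spad_slope: 1.1",
               "seed: 99"), path)
  cfg <- read_generator_config(path)
  expect_equal(cfg$chl_range, c(10, 50))
  expect_equal(cfg$noise_sd, 0.002)
  expect_equal(cfg$spad_slope, 1.1)
  expect_equal(cfg$seed, 99L)
  writeLines("nonsense_key: 3", path)
  expect_error(read_generator_config(path), "unknown config key")
})

test_that("dataset artifacts are written as plain-text tables", {
  dir <- tempfile()
  ds <- small_dataset(5)
  write_leaf_dataset(ds, dir, images = 2)
  expect_true(file.exists(file.path(dir, "spectra.csv")))
  resp <- read_responses_table(file.path(dir, "responses.csv"))
  expect_equal(resp$spad, ds$spad, tolerance = 1e-12)
  expect_length(list.files(file.path(dir, "images")), 2)
  expect_length(list.files(file.path(dir, "masks")), 2)
})
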