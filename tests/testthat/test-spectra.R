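test_that("spectra tables round-trip through CSV", {
  d <- spectral_dataset(c("a", "b"), c(500, 600, 700),
                        rbind(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)),
                        spad = c(20, 30))
  path <- tempfile(fileext = ".csv")
  write_spectra_table(d, path)
  d2 <- read_spectra_table(path, spad = c(20, 30))
  expect_equal(d2$wavelengths, d$wavelengths)
  expect_equal(unname(d2$reflectance), unname(d$reflectance), tolerance = 1e-12)
  expect_equal(d2$ids, d$ids)
})

test_that("malformed spectra tables are rejected with located errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,700,600,800", "a,0.1,0.2,0.3"), path)
  expect_error(read_spectra_table(path), "strictly increasing")
  writeLines(c("sample_id,600,700", "a,0.1,1.7"), path)
  expect_error(read_spectra_table(path), "outside \\[0, 1\\]")
  writeLines(c("sample_id,600,700", "a,0.1,oops"), path)
  expect_error(read_spectra_table(path), "non-numeric")
})

test_that("SNV centres and scales with the sample standard deviation", {
  s <- leaf_spectrum(c(1, 2, 3), c(0.2, 0.4, 0.6))
  expect_equal(snv(s)$reflectance, c(-1, 0, 1), tolerance = 1e-12)
  # idempotent on already standardised input
  z <- leaf_spectrum(1:5, c(-1.2649111, -0.6324555, 0, 0.6324555, 1.2649111),
                     preprocessed = TRUE)
  expect_equal(snv(z)$reflectance, z$reflectance, tolerance = 1e-6)
  expect_error(snv(leaf_spectrum(1:3, rep(0.3, 3))), "constant")
})

test_that("SNV output has mean zero and unit sd for every generated spectrum", {
  ds <- small_dataset(100, seed = 5)
  for (i in seq(1, 100, by = 7)) {
    z <- snv(get_spectrum(as_spectral_dataset(ds), i))$reflectance
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(stats::sd(z) - 1), 1e-10)
  }
})

test_that("SNV removes affine scatter exactly", {
  set.seed(3)
  x <- runif(200, 0.1, 0.6)
  s1 <- leaf_spectrum(1:200, x)
  s2 <- leaf_spectrum(1:200, pmin(1, 0.8 * x + 0.05))
  expect_equal(snv(s1)$reflectance, snv(s2)$reflectance, tolerance = 1e-9)
})

test_that("Savitzky-Golay reproduces low-order polynomials exactly", {
  w <- seq(400, 500, by = 2)
  for (p in 0:3) {
    sig <- 0.3 + 0.001 * (w - 450) + if (p >= 2) 1e-5 * (w - 450)^2 else 0
    if (p >= 3) sig <- sig + 1e-7 * (w - 450)^3
    s <- leaf_spectrum(w, sig, preprocessed = TRUE)
    out <- savitzky_golay(s, window = 9, polyorder = max(p, 2))
    expect_equal(out$reflectance, sig, tolerance = 1e-9)
  }
})

test_that("the 5-point quadratic smoother has impulse response 17/35 at centre", {
  imp <- leaf_spectrum(1:11, c(rep(0, 5), 1, rep(0, 5)), preprocessed = TRUE)
  out <- savitzky_golay(imp, window = 5, polyorder = 2)
  expect_equal(out$reflectance[6], 17 / 35, tolerance = 1e-12)
  # full interior response reproduces the classical weight vector
  expect_equal(out$reflectance[4:8], c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
})

test_that("Savitzky-Golay rejects invalid windows and non-uniform grids", {
  s <- leaf_spectrum(1:20, runif(20), preprocessed = TRUE)
  expect_error(savitzky_golay(s, window = 4), "odd")
  expect_error(savitzky_golay(s, window = 3, polyorder = 3), "exceed")
  bad <- leaf_spectrum(c(1:10, 12:21), runif(20), preprocessed = TRUE)
  expect_error(savitzky_golay(bad, window = 5), "uniform")
})

test_that("band lookup interpolates linearly and rejects out-of-range targets", {
  s <- leaf_spectrum(c(700, 710), c(0.2, 0.4))
  expect_equal(band_value(s, 700), 0.2)
  expect_equal(band_value(s, 705), 0.3)
  expect_error(band_value(s, 2600), "outside")
})

test_that("the 70/30 split reproduces the canonical 2520/1080 partition", {
  sp <- train_test_split(3600, 0.7, seed = 1)
  expect_length(sp$train, 2520)
  expect_length(sp$test, 1080)
})

test_that("splits are disjoint, exhaustive and deterministic", {
  sp <- train_test_split(10, 0.7, seed = 4)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_identical(sp, train_test_split(10, 0.7, seed = 4))
  expect_error(train_test_split(10, 1.2), "between 0 and 1")
})

test_that("split sizes follow round-half-up for every n up to 1000", {
  for (frac in c(0.5, 0.7)) {
    for (n in 2:1000) {
      expected <- min(n - 1L, max(1L, floor(n * frac + 0.5)))
      sp <- train_test_split(n, frac, seed = 1)
      expect_length(sp$train, expected)
    }
  }
})

test_that("dataset preprocessing smooths then standardises each spectrum", {
  ds <- as_spectral_dataset(small_dataset(5))
  pre <- preprocess_dataset(ds)
  expect_true(pre$preprocessed)
  for (i in 1:5) {
    expect_lt(abs(mean(pre$reflectance[i, ])), 1e-10)
    expect_lt(abs(stats::sd(pre$reflectance[i, ]) - 1), 1e-10)
  }
})
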