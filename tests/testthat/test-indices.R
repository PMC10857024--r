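test_that("every spectral index matches its independent oracle on random inputs", {
  set.seed(101)
  for (rep in 1:1000) {
    s <- random_band_spectrum()
    R <- as.list(stats::setNames(s$reflectance, as.character(s$wavelengths)))
    for (nm in svi_names()) {
      expected <- svi_oracles[[nm]](R)
      got <- compute_svi(s, nm)
      if (is.finite(expected) && abs(expected) < 1e6) {
        expect_equal(got, expected, tolerance = 1e-12,
                     label = sprintf("%s (rep %d)", nm, rep))
      }
    }
  }
})

test_that("every colour index matches its independent oracle on random inputs", {
  set.seed(202)
  for (rep in 1:1000) {
    ch <- stats::runif(3, 1, 255)
    cs <- color_sample(ch[1], ch[2], ch[3])
    for (nm in cvi_names()) {
      expected <- cvi_oracles[[nm]](ch[1], ch[2], ch[3])
      got <- compute_cvi(cs, nm)
      if (is.finite(expected) && abs(expected) < 1e6) {
        expect_equal(got, expected, tolerance = 1e-12,
                     label = sprintf("%s (rep %d)", nm, rep))
      }
    }
  }
})

test_that("worked spectral-index examples evaluate correctly", {
  s <- leaf_spectrum(c(559, 705, 750, 872), c(0.4, 0.2, 0.6, 0.4))
  expect_equal(compute_svi(s, "GRVI"), 1.0)
  expect_equal(compute_svi(s, "NDVI"), 0.5)
  s2 <- leaf_spectrum(c(531, 570), c(0.3, 0.3))
  expect_equal(compute_svi(s2, "PRI"), 0)
  s3 <- leaf_spectrum(c(550, 780), c(0.25, 0.5))
  expect_equal(compute_svi(s3, "CIgreen"), 1.0)
})

test_that("the two red-edge ratio rows are aliases of the same computation", {
  set.seed(5)
  s <- random_band_spectrum()
  expect_identical(compute_svi(s, "VOG2"), compute_svi(s, "VREI"))
})

test_that("worked colour-index examples evaluate correctly", {
  expect_equal(compute_cvi(color_sample(80, 120, 80), "IKAW"), 0)
  expect_equal(color_sample(50, 150, 50)$gn, 0.6)
  expect_equal(compute_cvi(color_sample(50, 150, 50), "gn"), 0.6)
  # NDI from rn = 0.2, gn = 0.6: channels (0.2, 0.6, 0.2) * total
  cs <- color_sample(40, 120, 40)
  expect_equal(compute_cvi(cs, "NDI"), (0.2 - 0.6) / (0.2 + 0.6 + 0.01),
               tolerance = 1e-12)
  expect_true(is.na(compute_cvi(color_sample(100, 100, 50), "WI")))
})

test_that("normalised-difference indices stay within [-1, 1] for positive inputs", {
  set.seed(33)
  for (rep in 1:200) {
    s <- random_band_spectrum()
    for (nm in c("NDVI", "NDVI1", "NDVI3D", "PRI", "Lic2", "NPCI")) {
      v <- compute_svi(s, nm)
      expect_gte(v, -1); expect_lte(v, 1)
    }
    ch <- stats::runif(3, 1, 255)
    v <- compute_cvi(color_sample(ch[1], ch[2], ch[3]), "IKAW")
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("unknown index names are reported with the valid vocabulary", {
  s <- random_band_spectrum()
  expect_error(compute_svi(s, "TCARI"), "valid names")
  expect_error(compute_cvi(color_sample(1, 2, 3), "nope"), "valid names")
})

test_that("feature tables have the expected shape per feature set", {
  ds <- small_dataset(30)
  fused <- build_feature_table(ds, "fused")
  expect_length(attr(fused, "feature_names"), 29)
  expect_true(all(c("sample_id", "spad") %in% colnames(fused)))
  svi <- build_feature_table(ds, "svi")
  expect_length(attr(svi, "feature_names"), 19)
  cvi <- build_feature_table(ds, "cvi")
  expect_length(attr(cvi, "feature_names"), 10)
  expect_error(build_feature_table(ds, index_names = character(0)), "non-empty")
})

test_that("colour indices require colour samples", {
  ds <- small_dataset(5)
  ds$rgb <- NULL
  expect_error(build_feature_table(ds, "cvi"), "no colour samples")
  expect_silent(suppressMessages(build_feature_table(ds, "svi")))
})

test_that("rows with undefined index values are dropped and counted", {
  ds <- small_dataset(4)
  ds$rgb$R <- c(100, 100, 50, 60)
  ds$rgb$G <- c(100, 120, 70, 80)  # row 1 has R == G: WI undefined
  ft <- suppressMessages(build_feature_table(ds, index_names = "WI"))
  expect_equal(nrow(ft), 3)
  expect_equal(attr(ft, "n_dropped"), 1L)
  kept <- build_feature_table(ds, index_names = "WI", na_action = "keep")
  expect_equal(nrow(kept), 4)
  expect_true(is.na(kept$WI[1]))
})

test_that("feature tables round-trip to delimited text", {
  ds <- small_dataset(10)
  ft <- build_feature_table(ds, "fused")
  path <- tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(colnames(back), colnames(ft))
  expect_equal(back$GRVI, ft$GRVI, tolerance = 1e-12)
})
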