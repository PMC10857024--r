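make_linear_table <- function(n = 300, p = 3, betas = NULL, intercept = 7,
                              noise = 0, seed = 1) {
  set.seed(seed)
  if (is.null(betas)) betas <- seq_len(p)
  x <- matrix(runif(n * p, 0, 10), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.numeric(x %*% betas + intercept + rnorm(n, 0, noise))
  ft <- data.frame(sample_id = sprintf("s%03d", seq_len(n)), x,
                   check.names = FALSE)
  ft$spad <- y
  attr(ft, "feature_names") <- colnames(x)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

test_that("the lognormal transform and its inverse are exact", {
  x <- matrix(c(1, exp(1), exp(2)), ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(as.numeric(lognormal_transform(x, 0)), c(0, 1, 2), tolerance = 1e-12)
  set.seed(4)
  m <- matrix(runif(60, 0.1, 9), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(lognormal_inverse(lognormal_transform(m, 2), 2), m,
               tolerance = 1e-12)
  bad <- matrix(c(1, -0.5), 2, 1, dimnames = list(NULL, "GRVI"))
  expect_error(lognormal_transform(bad, 0), "GRVI")
})

test_that("median imputation fills gaps and leaves complete columns unchanged", {
  ft <- make_linear_table(50, 3)
  complete_col <- ft$f2
  ft$f1[c(3, 7)] <- NA
  spec <- model_spec("rf", list(n_estimators = 50L))
  fit <- fit_pipeline(spec, ft)
  expect_equal(unname(fit$imputer["f2"]), stats::median(complete_col))
  # prediction succeeds on data with gaps in the same column
  nd <- as.data.frame(ft)[1:5, ]
  nd$f1[2] <- NA
  expect_length(predict(fit, nd), 5)
})

test_that("tree families reproduce a constant response", {
  ft <- make_linear_table(60, 2)
  ft$spad <- rep(17.5, 60)
  for (fam in c("et", "rf", "xgb", "lgbm")) {
    fit <- fit_pipeline(model_spec(fam), ft)
    pred <- predict(fit, ft)
    expect_equal(pred, rep(17.5, 60), tolerance = 1e-3,
                 label = paste(fam, "constant response"))
  }
})

test_that("PLSR recovers exact linear coefficients and matches the linear form", {
  betas <- c(2, -1, 0.5)
  ft <- make_linear_table(200, 3, betas = betas, intercept = 7, noise = 0)
  fit <- fit_pipeline(model_spec("plsr", list(ncomp = 3L)), ft)
  co <- coef(fit)
  expect_equal(unname(co$betas), betas, tolerance = 1e-6)
  expect_equal(co$intercept, 7, tolerance = 1e-6)
  x <- feature_matrix(ft)
  manual <- vapply(seq_len(10), function(i) {
    linear_prediction(co$betas, x[i, ], co$intercept)
  }, numeric(1))
  expect_equal(manual, predict(fit, ft)[1:10], tolerance = 1e-8)
})

test_that("prediction refuses tables missing training features", {
  ft <- make_linear_table(50, 3)
  fit <- fit_pipeline(model_spec("rf", list(n_estimators = 30L)), ft)
  nd <- as.data.frame(ft)[, c("f1", "f2", "spad")]
  expect_error(predict(fit, nd), "missing training feature")
})

test_that("svm and bpnn baselines fit an easy linear signal sensibly", {
  ft <- make_linear_table(250, 2, noise = 0.5, seed = 6)
  sp <- train_test_split(nrow(ft), 0.7, seed = 1)
  tr <- ft[sp$train, ]; te <- ft[sp$test, ]
  class(tr) <- class(te) <- class(ft)
  attr(tr, "feature_names") <- attr(te, "feature_names") <- attr(ft, "feature_names")
  for (fam in c("svm", "bpnn")) {
    fit <- fit_pipeline(model_spec(fam, seed = 2), tr)
    r2 <- r_squared(feature_response(te), predict(fit, te))
    expect_gt(r2, 0.9)
  }
})

test_that("random search is deterministic, ranked, and respects its budget", {
  ft <- make_linear_table(120, 2, noise = 1)
  cfg <- search_config(budget = 5, cv_folds = 3, seed = 42)
  res1 <- random_search(ft, cfg)
  res2 <- random_search(ft, cfg)
  expect_identical(res1$ranking, res2$ranking)
  expect_equal(nrow(res1$ranking), 5)
  expect_false(is.unsorted(res1$ranking$cv_mse))
  one <- random_search(ft, search_config(budget = 1, cv_folds = 3, seed = 1))
  expect_equal(nrow(one$ranking), 1)
})

test_that("the search finds a near-perfect model for a noiseless linear response", {
  ft <- make_linear_table(600, 2, betas = c(3, -2), noise = 0, seed = 11)
  sp <- train_test_split(nrow(ft), 0.7, seed = 3)
  tr <- ft[sp$train, ]; te <- ft[sp$test, ]
  class(tr) <- class(te) <- class(ft)
  attr(tr, "feature_names") <- attr(te, "feature_names") <- attr(ft, "feature_names")
  res <- random_search(tr, search_config(budget = 30, cv_folds = 5, seed = 7))
  best <- fit_pipeline(res$specs[[1]], tr)
  r2 <- r_squared(feature_response(te), predict(best, te))
  expect_gte(r2, 0.99)
})

test_that("search results serialise to a ranked delimited table", {
  ft <- make_linear_table(90, 2, noise = 1)
  res <- random_search(ft, search_config(budget = 3, cv_folds = 3, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_search_results(res, path)
  tab <- utils::read.csv(path)
  expect_equal(tab$rank, 1:3)
  expect_true(all(c("family", "cv_mse", "params") %in% colnames(tab)))
})

test_that("search configuration preconditions are enforced", {
  expect_error(search_config(budget = 0), "at least 1")
  expect_error(search_config(cv_folds = 1), "at least 2")
  ft <- make_linear_table(8, 2)
  expect_error(random_search(ft, search_config(budget = 1, cv_folds = 5)),
               "too small")
})
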