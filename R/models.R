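#' Regression model specification
#'
#' Describes one candidate pipeline of the model-search harness: a model
#' family, its hyperparameters, and whether the lognormal feature transform
#' is applied. Families:
#' \describe{
#'   \item{`et`}{extremely randomised trees (extra-trees) ensemble}
#'   \item{`xgb`}{gradient-boosted trees, depth-wise growth (XGBoost-style
#'     hyperparameter surface: `eta`, `max_depth`, `min_child_weight`,
#'     `n_estimators`)}
#'   \item{`lgbm`}{gradient-boosted trees, leaf-wise growth (LightGBM-style
#'     surface: `learning_rate`, `num_leaves`, `n_estimators`, unlimited
#'     depth when `max_depth = 0`)}
#'   \item{`rf`}{random forest}
#'   \item{`plsr`}{partial least squares regression (linear; exposes the
#'     coefficients of the linear prediction form)}
#'   \item{`svm`}{support vector regression, radial kernel, standardised
#'     features}
#'   \item{`bpnn`}{single-hidden-layer perceptron with weight-decay
#'     regularisation, standardised features and response}
#' }
#' Every pipeline starts with median imputation of missing feature values.
#'
#' @param family One of `"et"`, `"xgb"`, `"lgbm"`, `"rf"`, `"plsr"`,
#'   `"svm"`, `"bpnn"`.
#' @param params Named list of hyperparameters; omitted entries take the
#'   family defaults from [default_params()].
#' @param lognormal Logical; apply the lognormal feature transform (shift
#'   chosen from the training data so all shifted values are positive).
#' @param seed Integer seed for stochastic fits.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, params = list(), lognormal = FALSE, seed = 1L) {
  family <- match.arg(family, c("et", "xgb", "lgbm", "rf", "plsr", "svm", "bpnn"))
  full <- utils::modifyList(default_params(family), params)
  structure(list(family = family, params = full,
                 lognormal = isTRUE(lognormal), seed = as.integer(seed)),
            class = "model_spec")
}

#' Default hyperparameters per model family
#'
#' Tree-family defaults follow the hyperparameter sets an automated search
#' typically selects for this problem: extra-trees and depth-wise boosting
#' with 100 trees and depth 6 (learning rate 0.1, `min_child_weight` 1),
#' leaf-wise boosting with learning rate 0.1, 20 rounds, 31 leaves and no
#' depth limit, and a random forest with 482 trees of depth 25.
#'
#' @param family Family name as in [model_spec()].
#' @return Named list of hyperparameters.
#' @export
default_params <- function(family) {
  switch(family,
    et   = list(n_estimators = 100L, max_depth = 6L, min_samples = 2L),
    xgb  = list(eta = 0.1, max_depth = 6L, min_child_weight = 1,
                n_estimators = 100L),
    lgbm = list(learning_rate = 0.1, n_estimators = 20L, num_leaves = 31L,
                max_depth = 0L, min_child_samples = 20L,
                bagging_fraction = 0.9, bagging_freq = 0L),
    rf   = list(n_estimators = 482L, max_depth = 25L),
    plsr = list(ncomp = NA_integer_),  # NA: choose by inner CV, up to min(10, p)
    svm  = list(cost = 1, gamma = NA_real_),  # NA gamma: 1/p
    bpnn = list(hidden = 64L, decay = 1e-3, maxit = 200L),
    stop(sprintf("unknown family '%s'", family), call. = FALSE))
}

#' Lognormal feature transform and its inverse
#'
#' Elementwise natural logarithm of `value + shift`. Every shifted value
#' must be strictly positive; a violation is reported with the offending
#' column. The inverse restores the original values.
#'
#' @param x Numeric matrix or data frame of features.
#' @param shift Scalar added before taking logs.
#' @return Transformed matrix of the same shape.
#' @examples
#' lognormal_transform(matrix(c(1, exp(1), exp(2))), shift = 0)
#' @export
lognormal_transform <- function(x, shift = 0) {
  x <- as.matrix(x)
  shifted <- x + shift
  if (any(shifted <= 0, na.rm = TRUE)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    cn <- colnames(x)[bad[2]]
    stop(sprintf("lognormal transform undefined: value %g + shift %g <= 0 in column %s",
                 x[bad[1], bad[2]], shift,
                 if (is.null(cn)) as.character(bad[2]) else cn), call. = FALSE)
  }
  log(shifted)
}

#' @rdname lognormal_transform
#' @export
lognormal_inverse <- function(x, shift = 0) {
  exp(as.matrix(x)) - shift
}

# Median imputer: parameters learned on the training features only.
fit_imputer <- function(x) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

apply_imputer <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

# Resolve a feature_table or matrix into (x, y).
resolve_xy <- function(train) {
  if (inherits(train, "feature_table")) {
    list(x = feature_matrix(train), y = feature_response(train))
  } else if (is.list(train) && !is.null(train$x)) {
    list(x = as.matrix(train$x), y = train$y)
  } else {
    stop("train must be a feature_table or a list(x, y)", call. = FALSE)
  }
}

#' Fit a model pipeline
#'
#' Fits the full pipeline described by a [model_spec()]: median imputation,
#' optional lognormal transform (shift derived from the training data so
#' all shifted values are at least 1), then the family's model. The fitted
#' object remembers its training feature names and refuses to predict on a
#' table missing any of them.
#'
#' @param spec A [model_spec()].
#' @param train A `feature_table` (or `list(x, y)`).
#' @return An object of class `fitted_pipeline`.
#' @export
fit_pipeline <- function(spec, train) {
  stopifnot(inherits(spec, "model_spec"))
  xy <- resolve_xy(train)
  x <- xy$x; y <- xy$y
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty feature table", call. = FALSE)
  med <- fit_imputer(x)
  x <- apply_imputer(x, med)
  shift <- 0
  if (spec$lognormal) {
    shift <- max(0, -min(x)) + 1
    x <- lognormal_transform(x, shift)
  }
  set.seed(spec$seed)
  model <- fit_family(spec$family, spec$params, x, y)
  structure(
    list(spec = spec, model = model, feature_names = colnames(xy$x),
         imputer = med, shift = shift),
    class = "fitted_pipeline"
  )
}

fit_family <- function(family, p, x, y) {
  df <- as.data.frame(x)
  df$.y <- y
  switch(family,
    et = ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = p$n_estimators, max.depth = p$max_depth,
      mtry = ncol(x), min.node.size = p$min_samples,
      splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1,
      num.threads = 1L, seed = sample.int(.Machine$integer.max, 1)),
    rf = ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = p$n_estimators, max.depth = p$max_depth,
      mtry = ncol(x),
      num.threads = 1L, seed = sample.int(.Machine$integer.max, 1)),
    xgb = xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = p$eta,
                    max_depth = p$max_depth,
                    min_child_weight = p$min_child_weight,
                    nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = p$n_estimators, verbose = 0),
    lgbm = xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    eta = p$learning_rate,
                    tree_method = "hist", grow_policy = "lossguide",
                    max_depth = p$max_depth,       # 0 = no depth limit
                    max_leaves = p$num_leaves,
                    min_child_weight = p$min_child_samples,
                    subsample = if (p$bagging_freq > 0) p$bagging_fraction else 1,
                    nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = p$n_estimators, verbose = 0),
    plsr = fit_plsr(x, y, p$ncomp),
    svm = e1071::svm(x = x, y = y, kernel = "radial", cost = p$cost,
                     gamma = if (is.na(p$gamma)) 1 / ncol(x) else p$gamma,
                     scale = TRUE),
    bpnn = fit_bpnn(x, y, p),
    stop(sprintf("unknown family '%s'", family), call. = FALSE))
}

# PLS1 via mixOmics; number of components chosen by 5-fold CV when not fixed.
# Prediction is always the linear form x %*% betas + intercept, which the
# centred PLS regression model reduces to. A single feature is plain OLS.
fit_plsr <- function(x, y, ncomp = NA_integer_) {
  if (ncol(x) == 1L) {
    fit <- stats::lm(y ~ x[, 1])
    return(list(ncomp = 1L,
                betas = stats::setNames(unname(stats::coef(fit)[2]), colnames(x)),
                intercept = unname(stats::coef(fit)[1])))
  }
  max_comp <- min(10L, ncol(x), nrow(x) - 1L)
  if (is.na(ncomp)) {
    if (max_comp == 1L) {
      ncomp <- 1L
    } else {
      folds <- cut(sample(nrow(x)), breaks = 5, labels = FALSE)
      errs <- rep(0, max_comp)
      for (f in 1:5) {
        tr <- folds != f
        if (sum(tr) <= max_comp) next
        fit <- mixOmics::pls(x[tr, , drop = FALSE], y[tr], ncomp = max_comp,
                             mode = "regression", scale = FALSE)
        pr <- predict(fit, x[!tr, , drop = FALSE])$predict
        for (k in 1:max_comp) errs[k] <- errs[k] + sum((y[!tr] - pr[, 1, k])^2)
      }
      ncomp <- which.min(errs)
    }
  }
  ncomp <- min(ncomp, max_comp)
  fit <- mixOmics::pls(x, y, ncomp = ncomp, mode = "regression", scale = FALSE)
  betas <- predict(fit, x[1, , drop = FALSE])$B.hat[, 1, ncomp]
  intercept <- mean(y) - sum(colMeans(x) * betas)
  list(ncomp = ncomp, betas = betas, intercept = intercept)
}

fit_bpnn <- function(x, y, p) {
  xm <- colMeans(x); xs <- apply(x, 2, stats::sd); xs[xs == 0] <- 1
  ym <- mean(y); ys <- stats::sd(y); if (ys == 0) ys <- 1
  xz <- scale(x, xm, xs)
  net <- nnet::nnet(xz, (y - ym) / ys, size = p$hidden, linout = TRUE,
                    decay = p$decay, maxit = p$maxit,
                    MaxNWts = 100000L, trace = FALSE)
  list(net = net, xm = xm, xs = xs, ym = ym, ys = ys)
}

#' Predict SPAD values from a fitted pipeline
#'
#' @param object A `fitted_pipeline`.
#' @param newdata A `feature_table`, data frame or matrix containing at
#'   least the training feature columns (missing columns are a schema
#'   error; extra columns are ignored).
#' @param ... Unused.
#' @return Numeric vector of predictions, one per input row.
#' @export
predict.fitted_pipeline <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) {
    newdata <- as.data.frame(newdata)
  }
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_cols) > 0) {
    stop(sprintf("prediction table is missing training feature(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  x <- apply_imputer(x, object$imputer)
  if (object$spec$lognormal) {
    # values that fall below the training-derived shift are floored to keep
    # the transform defined at predict time
    x <- log(pmax(x + object$shift, 1e-9))
  }
  predict_family(object$spec$family, object$model, x)
}

predict_family <- function(family, model, x) {
  switch(family,
    et = ,
    rf = stats::predict(model, data = as.data.frame(x),
                        num.threads = 1L)$predictions,
    xgb = ,
    lgbm = stats::predict(model, x),
    plsr = as.numeric(x %*% model$betas + model$intercept),
    svm = as.numeric(stats::predict(model, x)),
    bpnn = {
      xz <- scale(x, model$xm, model$xs)
      as.numeric(stats::predict(model$net, xz)) * model$ys + model$ym
    })
}

#' Linear coefficients of a fitted PLSR pipeline
#'
#' For the linear family the prediction is exactly the linear form
#' `sum(beta_i * H_i) + C`; this accessor exposes the coefficients `beta`
#' and intercept `C` on the original (imputed, optionally log-transformed)
#' feature scale.
#'
#' @param object A `fitted_pipeline` with family `"plsr"`.
#' @param ... Unused.
#' @return List with `betas` (named) and `intercept`.
#' @export
coef.fitted_pipeline <- function(object, ...) {
  if (object$spec$family != "plsr") {
    stop("linear coefficients are only exposed for the plsr family", call. = FALSE)
  }
  list(betas = object$model$betas, intercept = object$model$intercept)
}

#' Search configuration for the model-search harness
#'
#' @param budget Number of candidate pipelines to sample (>= 1).
#' @param cv_folds Inner cross-validation folds (>= 2).
#' @param families Families to sample from (the automated-search set:
#'   tree ensembles).
#' @param search_lognormal Logical; also sample the lognormal preprocessing
#'   flag.
#' @param seed Integer seed; the search is deterministic given the seed.
#' @return An object of class `search_config`.
#' @export
search_config <- function(budget = 30L, cv_folds = 5L,
                          families = c("et", "xgb", "lgbm", "rf"),
                          search_lognormal = TRUE, seed = 1L) {
  budget <- as.integer(budget); cv_folds <- as.integer(cv_folds)
  if (budget < 1) stop("budget must be at least 1", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be at least 2", call. = FALSE)
  structure(list(budget = budget, cv_folds = cv_folds,
                 families = families,
                 search_lognormal = isTRUE(search_lognormal),
                 objective = "mse", seed = as.integer(seed)),
            class = "search_config")
}

# Uniform hyperparameter draw per family; ranges bracket the defaults of
# default_params().
sample_params <- function(family) {
  switch(family,
    et   = list(n_estimators = sample(50:300, 1),
                max_depth = sample(4:25, 1),
                min_samples = sample(1:5, 1)),
    xgb  = list(eta = 10^stats::runif(1, -2, log10(0.3)),
                max_depth = sample(3:10, 1),
                min_child_weight = sample(1:10, 1),
                n_estimators = sample(50:300, 1)),
    lgbm = list(learning_rate = 10^stats::runif(1, -2, log10(0.3)),
                n_estimators = sample(20:300, 1),
                num_leaves = sample(15:63, 1),
                max_depth = 0L,
                min_child_samples = sample(5:30, 1),
                bagging_fraction = stats::runif(1, 0.7, 1),
                bagging_freq = 0L),
    rf   = list(n_estimators = sample(100:600, 1),
                max_depth = sample(5:25, 1)))
}

#' Random search over model families and hyperparameters
#'
#' Re-implements the automated model-search protocol as a pinned, testable
#' procedure: `budget` candidate pipelines are sampled uniformly (family,
#' hyperparameters from ranges bracketing the family defaults, and
#' optionally the lognormal preprocessing flag), each is scored by k-fold
#' cross-validated mean squared error computed on the training partition
#' only, and candidates are returned ranked by ascending CV-MSE. The search
#' never sees held-out data, and is deterministic given the seed.
#'
#' @param train A `feature_table` (training partition only).
#' @param config A [search_config()].
#' @return An object of class `search_results`: list with `ranking` (data
#'   frame: rank, family, lognormal, cv_mse, params) and `specs` (list of
#'   [model_spec()] in ranked order).
#' @export
random_search <- function(train, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  xy <- resolve_xy(train)
  n <- nrow(xy$x)
  if (n == 0 || ncol(xy$x) == 0) stop("empty feature table", call. = FALSE)
  if (n < 2 * config$cv_folds) {
    stop("training set too small for the requested number of folds", call. = FALSE)
  }
  set.seed(config$seed)
  folds <- sample(rep(seq_len(config$cv_folds), length.out = n))
  candidates <- lapply(seq_len(config$budget), function(b) {
    family <- sample(config$families, 1)
    lognormal <- if (config$search_lognormal) sample(c(FALSE, TRUE), 1) else FALSE
    model_spec(family, sample_params(family), lognormal = lognormal,
               seed = config$seed + b)
  })
  cv_mse <- vapply(candidates, function(spec) {
    sse <- 0
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      fit <- fit_pipeline(spec, list(x = xy$x[tr, , drop = FALSE], y = xy$y[tr]))
      pred <- predict(fit, xy$x[!tr, , drop = FALSE])
      sse <- sse + sum((xy$y[!tr] - pred)^2)
    }
    sse / n
  }, numeric(1))
  ord <- order(cv_mse)
  ranking <- data.frame(
    rank = seq_along(ord),
    family = vapply(candidates[ord], function(s) s$family, character(1)),
    lognormal = vapply(candidates[ord], function(s) s$lognormal, logical(1)),
    cv_mse = cv_mse[ord],
    params = vapply(candidates[ord], function(s) {
      paste(sprintf("%s=%s", names(s$params),
                    vapply(s$params, function(v) format(v, digits = 4), character(1))),
            collapse = "; ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(ranking = ranking, specs = candidates[ord]),
            class = "search_results")
}

#' @export
print.search_results <- function(x, ...) {
  cat(sprintf("<search_results> %d candidates; best: %s (cv_mse = %.4g)\n",
              nrow(x$ranking), x$ranking$family[1], x$ranking$cv_mse[1]))
  invisible(x)
}

#' Write ranked search results as delimited text
#' @param results A `search_results`.
#' @param path Output CSV path (rank, family, lognormal, cv_mse, params).
#' @return `path`, invisibly.
#' @export
write_search_results <- function(results, path) {
  utils::write.csv(results$ranking, path, row.names = FALSE)
  invisible(path)
}
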