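#' Colour sample of a segmented leaf region
#'
#' Holds the mean 8-bit red, green and blue channel values of a leaf region
#' together with the normalised channels `rn = R / (R + G + B)`,
#' `gn = G / (R + G + B)` and `bn = B / (R + G + B)`. When `R + G + B` is
#' zero the normalised channels are undefined (`NA`).
#'
#' @param R,G,B Channel means in \[0, 255\].
#' @return An object of class `color_sample`.
#' @examples
#' color_sample(50, 150, 50)$gn  # 0.6
#' @export
color_sample <- function(R, G, B) {
  ch <- c(R, G, B)
  if (any(!is.finite(ch)) || any(ch < 0) || any(ch > 255)) {
    stop("R, G, B must lie in [0, 255]", call. = FALSE)
  }
  tot <- R + G + B
  structure(
    list(R = R, G = G, B = B,
         rn = if (tot > 0) R / tot else NA_real_,
         gn = if (tot > 0) G / tot else NA_real_,
         bn = if (tot > 0) B / tot else NA_real_),
    class = "color_sample"
  )
}

#' @export
print.color_sample <- function(x, ...) {
  cat(sprintf("<color_sample> R=%g G=%g B=%g\n", x$R, x$G, x$B))
  invisible(x)
}

# Ratio guard: a denominator within 1e-12 of zero makes the index undefined
# (NA marker), never an exception.
safe_div <- function(num, den) {
  if (!is.finite(den) || abs(den) < 1e-12) return(NA_real_)
  num / den
}

# Spectral vegetation index registry. Each entry: the reflectance bands it
# reads (nm) and its formula over those band values. Two naming notes:
# VOG2 and VREI are registered as aliases of the same red-edge ratio
# R740/R720 so that report tables can carry both rows; MCARI is implemented
# with R549 as the green reference band, the form used throughout the MCARI
# literature.
svi_registry <- list(
  NDVI    = list(bands = c(750, 705),
                 f = function(b) safe_div(b[["750"]] - b[["705"]], b[["750"]] + b[["705"]])),
  NDVI1   = list(bands = c(750, 680),
                 f = function(b) safe_div(b[["750"]] - b[["680"]], b[["750"]] + b[["680"]])),
  NDVI3D  = list(bands = c(780, 715),
                 f = function(b) safe_div(b[["780"]] - b[["715"]], b[["780"]] + b[["715"]])),
  VOG2    = list(bands = c(740, 720),
                 f = function(b) safe_div(b[["740"]], b[["720"]])),
  MSR1    = list(bands = c(750, 705, 445),
                 f = function(b) safe_div(b[["750"]] - b[["445"]], b[["705"]] - b[["445"]])),
  SIPI    = list(bands = c(800, 680, 445),
                 f = function(b) safe_div(b[["800"]] - b[["445"]], b[["800"]] - b[["680"]])),
  MDATT1  = list(bands = c(703, 732, 722),
                 f = function(b) safe_div(b[["703"]] - b[["732"]], b[["703"]] - b[["722"]])),
  MCARI   = list(bands = c(702, 671, 549),
                 f = function(b) {
                   ratio <- safe_div(b[["702"]], b[["671"]])
                   if (is.na(ratio)) return(NA_real_)
                   ((b[["702"]] - b[["671"]]) - 0.2 * (b[["702"]] - b[["549"]])) * ratio
                 }),
  GRVI    = list(bands = c(872, 559),
                 f = function(b) safe_div(b[["872"]], b[["559"]])),
  PRI     = list(bands = c(531, 570),
                 f = function(b) safe_div(b[["531"]] - b[["570"]], b[["531"]] + b[["570"]])),
  VARI    = list(bands = c(559, 661, 488),
                 f = function(b) safe_div(b[["559"]] - b[["661"]],
                                          b[["559"]] + b[["661"]] - b[["488"]])),
  VREI    = list(bands = c(740, 720),
                 f = function(b) safe_div(b[["740"]], b[["720"]])),
  SR      = list(bands = c(810, 550),
                 f = function(b) safe_div(b[["810"]], b[["550"]])),
  RVSI    = list(bands = c(722, 763, 733),
                 f = function(b) 0.5 * (b[["722"]] + b[["763"]]) - b[["733"]]),
  BGI1    = list(bands = c(450, 550),
                 f = function(b) safe_div(b[["450"]], b[["550"]])),
  Lic2    = list(bands = c(790, 680),
                 f = function(b) safe_div(b[["790"]] - b[["680"]], b[["790"]] + b[["680"]])),
  PSRI    = list(bands = c(680, 500, 750),
                 f = function(b) safe_div(b[["680"]] - b[["500"]], b[["750"]])),
  NPCI    = list(bands = c(642, 432),
                 f = function(b) safe_div(b[["642"]] - b[["432"]], b[["642"]] + b[["432"]])),
  CIgreen = list(bands = c(780, 550),
                 f = function(b) {
                   r <- safe_div(b[["780"]], b[["550"]])
                   if (is.na(r)) NA_real_ else r - 1
                 })
)

# Colour vegetation index registry over a color_sample. The three normalised
# channels double as indices in their own right.
cvi_registry <- list(
  rn   = function(cs) cs$rn,
  gn   = function(cs) cs$gn,
  bn   = function(cs) cs$bn,
  GRRI = function(cs) safe_div(cs$G, cs$R),
  RBRI = function(cs) safe_div(cs$R, cs$B),
  GBRI = function(cs) safe_div(cs$G, cs$B),
  IKAW = function(cs) safe_div(cs$R - cs$B, cs$R + cs$B),
  NDI  = function(cs) {
    if (is.na(cs$rn) || is.na(cs$gn)) return(NA_real_)
    safe_div(cs$rn - cs$gn, cs$rn + cs$gn + 0.01)
  },
  WI   = function(cs) safe_div(cs$G - cs$B, cs$R - cs$G),
  GLI  = function(cs) safe_div(2 * cs$G - cs$R - cs$B, 2 * cs$G + cs$R + cs$B)
)

#' Names of the registered vegetation indices
#' @return Character vector of index names.
#' @export
svi_names <- function() names(svi_registry)

#' @rdname svi_names
#' @export
cvi_names <- function() names(cvi_registry)

#' Compute one spectral vegetation index
#'
#' Evaluates the named index formula on reflectance values looked up with
#' [band_value()]. A denominator within 1e-12 of zero yields an undefined
#' marker (`NA`), not an error.
#'
#' @param spectrum A [leaf_spectrum()] whose range covers the index bands.
#' @param name Index name; see [svi_names()].
#' @return Numeric index value, or `NA` if undefined.
#' @examples
#' s <- leaf_spectrum(c(705, 750), c(0.2, 0.6))
#' compute_svi(s, "NDVI")  # 0.5
#' @export
compute_svi <- function(spectrum, name) {
  entry <- svi_registry[[name]]
  if (is.null(entry)) {
    stop(sprintf("unknown spectral index '%s'; valid names: %s",
                 name, paste(svi_names(), collapse = ", ")), call. = FALSE)
  }
  vals <- band_value(spectrum, entry$bands)
  names(vals) <- as.character(entry$bands)
  entry$f(as.list(vals))
}

#' Compute one colour vegetation index
#'
#' @param color A [color_sample()].
#' @param name Index name; see [cvi_names()].
#' @return Numeric index value, or `NA` if undefined (e.g. the Woebbecke
#'   index when `R = G`).
#' @examples
#' compute_cvi(color_sample(60, 180, 40), "IKAW")
#' @export
compute_cvi <- function(color, name) {
  f <- cvi_registry[[name]]
  if (is.null(f)) {
    stop(sprintf("unknown colour index '%s'; valid names: %s",
                 name, paste(cvi_names(), collapse = ", ")), call. = FALSE)
  }
  stopifnot(inherits(color, "color_sample"))
  f(color)
}

#' Assemble a feature table of vegetation indices with SPAD responses
#'
#' Builds the samples-by-indices design matrix used by the regression stage.
#' The feature set selects which modality is used: `"svi"` computes the 19
#' spectral indices from the dataset's spectra, `"cvi"` the 10 colour indices
#' from its RGB samples, and `"fused"` concatenates both (29 columns).
#' Alternatively `index_names` restricts the table to specific indices.
#' Rows where any requested index is undefined are dropped and the count is
#' reported via the `n_dropped` attribute (and a message); undefined values
#' are never silently zero-filled.
#'
#' @param dataset A `leaf_dataset` from [generate_dataset()], or any list
#'   with `ids`, `wavelengths`, `reflectance`, `spad`, and optionally `rgb`.
#' @param feature_set One of `"svi"`, `"cvi"`, `"fused"`.
#' @param index_names Optional character vector naming a subset of indices
#'   (spectral and/or colour); overrides `feature_set` membership.
#' @param na_action `"drop"` (default) removes incomplete rows;
#'   `"keep"` retains `NA` markers for downstream imputation.
#' @return A `data.frame` of class `feature_table` with a `sample_id` column,
#'   one named column per index, and a `spad` response column.
#' @export
build_feature_table <- function(dataset,
                                feature_set = c("fused", "svi", "cvi"),
                                index_names = NULL,
                                na_action = c("drop", "keep")) {
  feature_set <- match.arg(feature_set)
  na_action <- match.arg(na_action)
  if (!is.null(index_names) && length(index_names) == 0) {
    stop("index_names must be non-empty when supplied", call. = FALSE)
  }
  if (is.null(index_names)) {
    index_names <- switch(feature_set,
                          svi = svi_names(),
                          cvi = cvi_names(),
                          fused = c(svi_names(), cvi_names()))
  }
  unknown <- setdiff(index_names, c(svi_names(), cvi_names()))
  if (length(unknown) > 0) {
    stop(sprintf("unknown index name(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  want_svi <- intersect(index_names, svi_names())
  want_cvi <- intersect(index_names, cvi_names())
  if (length(want_cvi) > 0 && is.null(dataset$rgb)) {
    stop("colour indices requested but the dataset has no colour samples",
         call. = FALSE)
  }
  n <- length(dataset$ids)
  cols <- list()
  if (length(want_svi) > 0) {
    for (nm in want_svi) cols[[nm]] <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      s <- leaf_spectrum(dataset$wavelengths, dataset$reflectance[i, ],
                         preprocessed = isTRUE(dataset$preprocessed))
      for (nm in want_svi) cols[[nm]][i] <- compute_svi(s, nm)
    }
  }
  if (length(want_cvi) > 0) {
    css <- lapply(seq_len(n), function(i) {
      color_sample(dataset$rgb$R[i], dataset$rgb$G[i], dataset$rgb$B[i])
    })
    for (nm in want_cvi) {
      cols[[nm]] <- vapply(css, function(cs) {
        v <- compute_cvi(cs, nm)
        if (is.null(v) || is.na(v)) NA_real_ else v
      }, numeric(1))
    }
  }
  ft <- data.frame(sample_id = dataset$ids, cols, check.names = FALSE)
  ft$spad <- dataset$spad
  n_dropped <- 0L
  if (na_action == "drop") {
    keep <- stats::complete.cases(ft[, setdiff(colnames(ft), "sample_id"), drop = FALSE])
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      message(sprintf("build_feature_table: dropped %d row(s) with undefined index values",
                      n_dropped))
    }
    ft <- ft[keep, , drop = FALSE]
    rownames(ft) <- NULL
  }
  attr(ft, "n_dropped") <- n_dropped
  attr(ft, "feature_names") <- c(want_svi, want_cvi)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Feature and response accessors for a feature table
#' @param ft A `feature_table` from [build_feature_table()].
#' @return `feature_matrix()`: numeric matrix of index columns;
#'   `feature_response()`: numeric SPAD vector.
#' @export
feature_matrix <- function(ft) {
  nm <- attr(ft, "feature_names")
  if (is.null(nm)) nm <- setdiff(colnames(ft), c("sample_id", "spad"))
  as.matrix(as.data.frame(ft)[, nm, drop = FALSE])
}

#' @rdname feature_matrix
#' @export
feature_response <- function(ft) ft$spad

#' Write a feature table as delimited text
#' @param ft A `feature_table`.
#' @param path Output CSV path (`sample_id`, index columns, `spad`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  invisible(path)
}
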