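#' Segment the leaf region of an RGB plant image
#'
#' A deterministic classical segmenter standing in front of the colour
#' feature extraction: the excess-green transform `2G - R - B` is computed
#' per pixel, denoised with a 3x3 median filter (edge-preserving), thresholded
#' by between-class-variance maximisation (Otsu), and reduced to the single
#' largest connected component with interior holes filled. Plant material is
#' the excess-green-positive class, which separates green foliage from
#' soil-coloured or other non-green backgrounds.
#'
#' @param image Numeric `h x w x 3` array of 8-bit channel values (0-255),
#'   or values in \[0, 1\] which are rescaled.
#' @param median_radius Radius of the median denoising filter (pixels);
#'   0 disables it.
#' @return Logical `h x w` mask marking leaf pixels. A zero-variance image
#'   yields an empty mask with a warning.
#' @export
segment_leaf <- function(image, median_radius = 1L) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("image must be an h x w x 3 array", call. = FALSE)
  }
  if (max(image) <= 1) image <- image * 255
  exg <- 2 * image[, , 2] - image[, , 1] - image[, , 3]
  rng <- range(exg)
  if (diff(rng) < 1e-9) {
    warning("image has no contrast; returning empty mask")
    return(matrix(FALSE, nrow(exg), ncol(exg)))
  }
  norm <- (exg - rng[1]) / diff(rng)
  if (median_radius > 0) {
    norm <- EBImage::medianFilter(norm, as.integer(median_radius))
  }
  thr <- EBImage::otsu(norm, range = c(0, 1))
  mask <- norm > thr
  if (!any(mask)) {
    warning("threshold removed all pixels; returning empty mask")
    return(mask)
  }
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  as.matrix(EBImage::fillHull(mask)) > 0
}

#' Mean RGB colour of a masked image region
#'
#' Per-channel arithmetic mean over the mask pixels. The stored `R`, `G`,
#' `B` channels are rounded to the nearest integer; the normalised channels
#' `rn`, `gn`, `bn` are computed from the unrounded means.
#'
#' @param image Numeric `h x w x 3` array of 8-bit values.
#' @param mask Logical matrix of matching size with at least one `TRUE`.
#' @return A [color_sample()].
#' @export
mean_rgb <- function(image, mask) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("image must be an h x w x 3 array", call. = FALSE)
  }
  if (!identical(dim(mask), dim(image)[1:2])) {
    stop("mask dimensions must match the image", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty; nothing to average", call. = FALSE)
  means <- vapply(1:3, function(k) mean(image[, , k][mask]), numeric(1))
  tot <- sum(means)
  cs <- color_sample(round(means[1]), round(means[2]), round(means[3]))
  # normalised channels from the unrounded means
  if (tot > 0) {
    cs$rn <- means[1] / tot
    cs$gn <- means[2] / tot
    cs$bn <- means[3] / tot
  }
  cs
}

#' Intersection-over-union of two binary masks
#' @param a,b Logical matrices of equal size.
#' @return IoU in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Read an RGB image / write a binary mask as PNG
#' @param path PNG or JPEG path (PNG read natively).
#' @return `read_rgb_image()`: an `h x w x 3` array of 8-bit values.
#' @export
read_rgb_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3]
  img * 255
}

#' @rdname read_rgb_image
#' @param mask Logical matrix.
#' @return `write_mask_png()`: `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
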