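#' Nucleus segmentation pipeline
#'
#' Single-cell micrograph to binary nucleus mask: grayscale conversion,
#' histogram equalization, Sobel gradient, gradient-statistics thresholding,
#' morphological closing, largest-component selection, hole filling.
#'
#' @name segmentation
#' @keywords internal
NULL

clamp8 <- function(x) pmin(pmax(round(x), 0), 255)

#' Convert an RGB image to 8-bit grayscale
#'
#' Luminance conversion `0.299 R + 0.587 G + 0.114 B`, rounded to integers
#' in `[0, 255]`.
#'
#' @param image numeric array `a[row, col, channel]` with 3 channels,
#'   intensities on the 0--255 scale.
#' @return matrix of 8-bit intensities.
#' @export
to_grayscale <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("format error: expected a 3-channel RGB array")
  clamp8(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' Histogram equalization of an 8-bit grayscale image
#'
#' Standard 256-bin cumulative-distribution equalization. A constant image
#' (degenerate CDF) is returned unchanged.
#'
#' @param gray matrix of intensities in `[0, 255]`.
#' @return equalized matrix, same dimensions, intensities in `[0, 255]`.
#' @export
equalize_histogram <- function(gray) {
  if (!is.matrix(gray)) stop("format error: expected a grayscale matrix")
  gi <- clamp8(gray)
  h <- tabulate(gi + 1L, nbins = 256L)
  nz <- which(h > 0L)
  if (length(nz) <= 1L) return(gi)
  cdf <- cumsum(h)
  cdf_min <- cdf[nz[1L]]
  map <- round((cdf - cdf_min) / (length(gi) - cdf_min) * 255)
  matrix(map[gi + 1L], nrow(gray), ncol(gray))
}

#' Sobel gradient magnitude
#'
#' `sqrt(Gx^2 + Gy^2)` with the standard 3x3 Sobel kernels; image borders
#' are handled by edge replication.
#'
#' @param gray matrix of intensities.
#' @return matrix of gradient magnitudes (same dimensions).
#' @export
sobel_gradient <- function(gray) {
  if (!is.matrix(gray)) stop("format error: expected a grayscale matrix")
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- as.matrix(EBImage::filter2(gray, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(gray, t(kx), boundary = "replicate"))
  sqrt(gx^2 + gy^2)
}

#' Gradient-statistics threshold
#'
#' Computes the mean and standard deviation of the gradient image and the
#' band `[mean - sd, mean + sd]`. If every pixel already lies in the band,
#' pixels whose gradient equals the mean (within `eps_mean`, the nearest-
#' integer tolerance of the 8-bit original) are selected; otherwise pixels
#' inside the band are selected.
#'
#' @param gradient gradient magnitude matrix (nonconstant).
#' @param eps_mean tolerance, in gray levels, for "equal to the mean" in the
#'   degenerate all-in-band branch. Default 0.5.
#' @return logical mask.
#' @export
threshold_nucleus <- function(gradient, eps_mean = 0.5) {
  if (!is.matrix(gradient)) stop("format error: expected a gradient matrix")
  mg <- mean(gradient)
  sg <- sd(as.vector(gradient))
  # FFT-based convolution leaves ~1e-14 noise on structureless images; a
  # spread far below one gray level is numerically zero, not structure
  if (sg <= 1e-8) stop("threshold produced no region")
  lo <- mg - sg; hi <- mg + sg
  mask <- if (all(gradient >= lo & gradient <= hi)) {
    abs(gradient - mg) <= eps_mean
  } else {
    gradient >= lo & gradient <= hi
  }
  if (!any(mask)) stop("threshold produced no region")
  mask
}

#' Morphological closing, largest component, hole fill
#'
#' Closes the thresholded mask with a disc structuring element, keeps the
#' largest 8-connected component, and fills its enclosed holes so the
#' result is a single solid region.
#'
#' @param mask logical/binary matrix.
#' @param closing_radius disc radius in pixels (default 3).
#' @return logical mask with one solid 8-connected component.
#' @export
close_and_select_largest <- function(mask, closing_radius = 3) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("no nucleus region")
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
    mask <- t(as.matrix(EBImage::imageData(
      EBImage::closing(EBImage::Image(t(mask * 1)), brush)))) > 0
  }
  if (!any(mask)) stop("no nucleus region")
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  fill_holes(lab == which.max(sizes))
}

#' Segment the nucleus of a single-cell image
#'
#' Full pipeline: grayscale conversion (RGB input), histogram equalization,
#' Sobel gradient, gradient-statistics threshold, closing + largest
#' 8-connected component + hole fill.
#'
#' The gradient-statistics rule presumes the image is cropped tightly around
#' the nucleus (the nucleus should dominate the crop) and that the cytoplasm
#' is much less textured than the nucleus; see the package vignette.
#'
#' @param image RGB array `a[row, col, 3]` or grayscale matrix, 0--255 scale.
#' @param closing_radius disc radius for the closing step (default 3).
#' @param eps_mean tolerance for the degenerate threshold branch.
#' @return logical nucleus mask.
#' @export
segment_nucleus <- function(image, closing_radius = 3, eps_mean = 0.5) {
  gray <- if (is.array(image) && length(dim(image)) == 3L) to_grayscale(image)
          else if (is.matrix(image)) clamp8(image)
          else stop("format error: expected an RGB array or grayscale matrix")
  eq <- equalize_histogram(gray)
  g <- sobel_gradient(eq)
  close_and_select_largest(threshold_nucleus(g, eps_mean = eps_mean),
                           closing_radius = closing_radius)
}
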