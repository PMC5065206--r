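#' Readers and writers
#'
#' Images and masks as PNG (TIFF supported when the tiff package is
#' available), contours as two-column CSV.
#'
#' @name io
#' @keywords internal
NULL

#' Read an image file
#'
#' PNG via the png package, TIFF via the tiff package. Intensities are
#' rescaled to the 0--255 working range; single-channel files come back as a
#' matrix, multi-channel files as an array (an alpha channel is dropped).
#'
#' @param path file path.
#' @return matrix or 3-channel array, intensities in 0--255.
#' @export
read_image <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  a <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else stop("unsupported image format: .", ext)
  a <- a * 255
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 1L) a <- a[, , 1]
    else if (dim(a)[3] >= 3L) a <- a[, , 1:3]
  }
  a
}

#' Write a grayscale image or binary mask as PNG
#'
#' Masks (logical) are written as 0/255.
#'
#' @param x matrix (grayscale, 0--255) or logical mask.
#' @param path output path.
#' @export
write_image <- function(x, path) {
  if (is.logical(x)) x <- x * 255
  png::writePNG(pmin(pmax(x, 0), 255) / 255, path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path file path.
#' @return logical matrix (pixels above half intensity are foreground).
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (length(dim(img)) == 3L) img <- to_grayscale(img)
  img > 127.5
}

#' Read / write an ordered contour as CSV
#'
#' Two columns `x`, `y` with header, one boundary point per row, in trace
#' order.
#'
#' @param path file path.
#' @return matrix with columns `x`, `y`.
#' @export
read_contour <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df))) stop("contour CSV needs x,y columns")
  as.matrix(df[, c("x", "y")])
}

#' @rdname read_contour
#' @param contour two-column matrix of points.
#' @export
write_contour <- function(contour, path) {
  if (is.data.frame(contour)) contour <- as.matrix(contour)
  colnames(contour) <- c("x", "y")
  write.csv(as.data.frame(contour), path, row.names = FALSE)
  invisible(path)
}
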