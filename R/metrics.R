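#' Classic nuclear shape metrics
#'
#' The three comparison metrics: radial asymmetry (RA), shape factor (SF)
#' and rim difference (RD).
#'
#' @name comparison_metrics
#' @keywords internal
NULL

#' Shape factor
#'
#' `SF = Perimeter^2 / (4 * pi * Area)`. Equals 1 for a perfect circle and
#' grows with boundary irregularity (isoperimetric inequality).
#'
#' @param perimeter positive perimeter (pixels).
#' @param area positive area (pixels^2).
#' @return dimensionless SF.
#' @export
shape_factor <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0)) stop("perimeter and area must be positive")
  perimeter^2 / (4 * pi * area)
}

#' Rim difference
#'
#' Excess of the contour length over the circumference of the circle with
#' the same area: `RD = P - 2 * sqrt(pi * A)` (`type = "absolute"`), or the
#' corresponding ratio `P / (2 * sqrt(pi * A))` (`type = "ratio"`). Zero
#' (respectively one) for a perfect circle.
#'
#' @param perimeter positive perimeter (pixels).
#' @param area positive area (pixels^2).
#' @param type `"absolute"` (pixels) or `"ratio"` (dimensionless).
#' @return RD.
#' @export
rim_difference <- function(perimeter, area, type = c("absolute", "ratio")) {
  type <- match.arg(type)
  if (any(perimeter <= 0) || any(area <= 0)) stop("perimeter and area must be positive")
  circ <- 2 * sqrt(pi * area)
  if (type == "absolute") perimeter - circ else perimeter / circ
}

#' Radial asymmetry
#'
#' The largest circle centered at the contour centroid that fits inside the
#' region has radius `r_in = min(d_i)` (minimum centroid-to-contour
#' distance). RA is the fraction of foreground pixels lying outside that
#' inscribed circle. Zero for a centered disk (up to discretization) and
#' larger for elongated or notched nuclei.
#'
#' @param mask binary nucleus mask.
#' @param contour optional precomputed contour (from [extract_contour()]).
#' @param centroid optional precomputed centroid.
#' @return RA in `[0, 1]`.
#' @export
radial_asymmetry <- function(mask, contour = NULL, centroid = NULL) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("no nucleus region")
  if (is.null(contour)) contour <- extract_contour(mask)
  if (is.null(centroid)) centroid <- compute_centroid(contour)
  r_in <- min(radial_distances(contour, centroid))
  idx <- which(mask, arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1
  dist <- sqrt((px - centroid[["x"]])^2 + (py - centroid[["y"]])^2)
  mean(dist > r_in)
}

#' All three classic metrics of a nucleus mask
#'
#' @param mask binary nucleus mask (single solid component).
#' @param perimeter_method passed to [contour_perimeter()].
#' @return named list with `ra`, `sf`, `rd` plus the `perimeter`, `area`,
#'   `contour` and `centroid` used.
#' @export
classic_metrics <- function(mask, perimeter_method = "kulpa") {
  mask <- as_mask(mask)
  contour <- extract_contour(mask)
  centroid <- compute_centroid(contour)
  p <- contour_perimeter(contour, method = perimeter_method)
  a <- region_area(mask)
  list(ra = radial_asymmetry(mask, contour, centroid),
       sf = shape_factor(p, a),
       rd = rim_difference(p, a),
       perimeter = p, area = a, contour = contour, centroid = centroid)
}
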