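#' Synthetic nucleus generator
#'
#' Star-shaped nuclear contours with controllable irregularity, emulating
#' the three diagnostic classes: NILM (near-circular, smooth), LSIL
#' (moderate low-frequency harmonic variability, occasional notch) and HSIL
#' (stronger harmonics plus localized notches/grooves). Shapes are defined
#' by an analytic radial function r(theta) and rasterized on a pixel grid,
#' so every score can be exercised without real micrographs.
#'
#' @name synthetic
#' @keywords internal
NULL

#' Specification of one synthetic nucleus shape
#'
#' The radial function is
#' `r(theta) = e(theta) + sum(amp * cos(freq * theta + phase)) -
#'  sum(depth * exp(-0.5 * (wrap(theta - angle) / width)^2)) + noise`,
#' where `e(theta)` is the radial function of an ellipse with axis ratio
#' `ellipticity` and geometric mean radius `base_radius`, the cosine terms
#' are membrane harmonics, the Gaussian-bump terms are localized notches,
#' and `noise` is seeded Gaussian radial jitter (sigma `noise_sigma`) drawn
#' once per boundary sample.
#'
#' @param base_radius mean radius in pixels (>= 10).
#' @param ellipticity axis ratio a/b (>= 1).
#' @param harmonics matrix/data frame with columns `freq`, `amp`, `phase`
#'   (or NULL).
#' @param notches matrix/data frame with columns `angle`, `depth`, `width`
#'   (radians, pixels, radians) or NULL.
#' @param noise_sigma radial jitter standard deviation in pixels.
#' @param seed integer seed making the jitter reproducible.
#' @return object of class `shape_spec`.
#' @export
shape_spec <- function(base_radius = 45, ellipticity = 1, harmonics = NULL,
                       notches = NULL, noise_sigma = 0, seed = 1L) {
  if (base_radius < 10) stop("base_radius must be >= 10 pixels")
  if (ellipticity < 1) stop("ellipticity must be >= 1")
  norm_tab <- function(x, cols) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (ncol(x) != length(cols)) stop("expected columns: ", paste(cols, collapse = ", "))
    colnames(x) <- cols
    x
  }
  harmonics <- norm_tab(harmonics, c("freq", "amp", "phase"))
  notches <- norm_tab(notches, c("angle", "depth", "width"))
  pert <- (if (is.null(harmonics)) 0 else sum(abs(harmonics[, "amp"]))) +
          (if (is.null(notches)) 0 else sum(abs(notches[, "depth"])))
  if (pert >= base_radius)
    stop("self-intersecting parameterization: perturbations exceed base radius")
  structure(list(base_radius = base_radius, ellipticity = ellipticity,
                 harmonics = harmonics, notches = notches,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "shape_spec")
}

# Analytic radial function (before jitter) evaluated at angles theta.
radial_function <- function(spec, theta) {
  a <- spec$base_radius * sqrt(spec$ellipticity)
  b <- spec$base_radius / sqrt(spec$ellipticity)
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  h <- spec$harmonics
  if (!is.null(h)) for (i in seq_len(nrow(h)))
    r <- r + h[i, "amp"] * cos(h[i, "freq"] * theta + h[i, "phase"])
  no <- spec$notches
  if (!is.null(no)) for (i in seq_len(nrow(no))) {
    dtheta <- (theta - no[i, "angle"] + pi) %% (2 * pi) - pi
    r <- r - no[i, "depth"] * exp(-0.5 * (dtheta / no[i, "width"])^2)
  }
  r
}

#' Rasterize a shape specification into a contour and mask
#'
#' The radial function is sampled at roughly 1-pixel arc resolution, seeded
#' radial jitter is added, and the star-shaped region
#' `{(x, y): dist <= r(theta)}` is rasterized on a square canvas (the
#' nucleus fills most of it, emulating a tight crop around the nucleus).
#' The pixel contour is then traced from the mask with [extract_contour()].
#'
#' @param spec a [shape_spec()].
#' @param margin background margin (pixels) beyond the maximum radius.
#' @return object of class `synthetic_nucleus`: list with `mask`, `contour`,
#'   `center` (0-based x, y of the canvas center), `theta`/`r` (the sampled
#'   radial function, for oracle use) and `spec`.
#' @export
make_contour <- function(spec, margin = 2) {
  stopifnot(inherits(spec, "shape_spec"))
  ntheta <- max(64L, ceiling(2 * pi * (spec$base_radius * sqrt(spec$ellipticity) + 10)))
  theta <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  r <- radial_function(spec, theta)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    r <- r + rnorm(ntheta, 0, spec$noise_sigma)
  }
  if (any(r < 3)) stop("self-intersecting parameterization: radius collapses")
  rmax <- max(r)
  half <- ceiling(rmax + margin)
  n <- 2L * half + 1L
  c0 <- half  # 0-based center coordinate
  px <- matrix(rep(0:(n - 1L), each = n), n, n)   # x = col - 1 over columns
  py <- matrix(rep(0:(n - 1L), times = n), n, n)  # y = row - 1 over rows
  ang <- atan2(py - c0, px - c0) %% (2 * pi)
  rad <- sqrt((px - c0)^2 + (py - c0)^2)
  # interpolate the sampled radial function periodically
  rq <- stats::approx(c(theta, 2 * pi), c(r, r[1]), xout = ang, rule = 2)$y
  mask <- rad <= rq
  # radial jitter can pinch off fragments or leave single pixels attached
  # only diagonally; the generator guarantees a single solid 4-edge-connected
  # region, so keep the largest piece, prune diagonal spurs, and fill holes
  lab <- label8(mask)
  if (max(lab) > 1L) mask <- lab == which.max(tabulate(lab[lab > 0L]))
  mask <- fill_holes(prune_diagonal_spurs(mask))
  structure(list(mask = mask, contour = extract_contour(mask),
                 center = c(x = c0, y = c0), theta = theta, r = r,
                 spec = spec),
            class = "synthetic_nucleus")
}

#' @export
plot.synthetic_nucleus <- function(x, ...) {
  image(t(x$mask)[, nrow(x$mask):1], col = gray(c(1, 0.4)), axes = FALSE,
        asp = 1, ...)
  invisible(x)
}

#' Render a synthetic nucleus as a grayscale micrograph
#'
#' Dark nucleus on a lighter homogeneous background. Chromatin granularity
#' is modeled as Gaussian texture inside the nucleus (`texture_sigma`);
#' optional global sensor noise (`noise_sigma`) is added everywhere. The
#' gradient-statistics segmentation assumes a low-texture background; its
#' robustness degrades quickly once global sensor noise exceeds a fraction
#' of a gray level (see the vignette), hence the default of 0.
#'
#' @param nucleus a `synthetic_nucleus` (or bare logical mask).
#' @param fg nucleus intensity (default 60).
#' @param bg background intensity (default 180).
#' @param texture_sigma chromatin texture sd inside the nucleus (default 10).
#' @param noise_sigma global additive sensor noise sd (default 0).
#' @param seed seed for texture and noise.
#' @return list with `image` (8-bit matrix) and `mask` (ground truth).
#' @export
render_image <- function(nucleus, fg = 60, bg = 180, texture_sigma = 10,
                         noise_sigma = 0, seed = 1L) {
  mask <- if (inherits(nucleus, "synthetic_nucleus")) nucleus$mask else as_mask(nucleus)
  set.seed(seed)
  img <- matrix(bg, nrow(mask), ncol(mask))
  img[mask] <- fg + if (texture_sigma > 0) rnorm(sum(mask), 0, texture_sigma) else 0
  if (noise_sigma > 0) img <- img + rnorm(length(img), 0, noise_sigma)
  list(image = clamp8(img), mask = mask)
}

#' Draw a random shape specification for a diagnostic class
#'
#' Class parameter distributions (defaults of the synthetic study design):
#' * `NILM`: near-circular; 2 weak low-frequency harmonics (amplitude up to
#'   0.6 px), no notches, slight radial jitter.
#' * `LSIL`: mild ellipticity; 3 harmonics of 0.8--2.5 px at frequencies
#'   3--8; a notch (2--5 px deep) in half the cells; moderate jitter.
#' * `HSIL`: up to 1.3 ellipticity; 4 harmonics of 1.5--3.5 px at
#'   frequencies 4--12; 1--3 notches 4--8 px deep; strongest jitter.
#'
#' The LSIL and HSIL parameter ranges overlap by design, mirroring the
#' morphological overlap of the two lesion grades.
#'
#' @param class `"NILM"`, `"LSIL"` or `"HSIL"`.
#' @param seed integer seed.
#' @param base_radius_range uniform range of the base radius in pixels.
#' @return a [shape_spec()].
#' @export
random_shape_spec <- function(class = c("NILM", "LSIL", "HSIL"), seed = 1L,
                              base_radius_range = c(35, 55)) {
  class <- match.arg(class)
  set.seed(seed)
  base <- runif(1, base_radius_range[1], base_radius_range[2])
  harm <- function(nh, fmin, fmax, amin, amax) {
    cbind(freq = sample(fmin:fmax, nh, replace = TRUE),
          amp = runif(nh, amin, amax),
          phase = runif(nh, 0, 2 * pi))
  }
  notch <- function(nn, dmin, dmax, wmin, wmax) {
    if (nn == 0L) return(NULL)
    cbind(angle = runif(nn, 0, 2 * pi),
          depth = runif(nn, dmin, dmax),
          width = runif(nn, wmin, wmax))
  }
  par <- switch(class,
    NILM = list(ell = runif(1, 1, 1.10), h = harm(2, 2, 4, 0, 0.6),
                no = NULL, ns = runif(1, 0.1, 0.3)),
    LSIL = list(ell = runif(1, 1, 1.20), h = harm(3, 3, 8, 0.8, 2.5),
                no = notch(stats::rbinom(1, 1, 0.5), 2, 5, 0.2, 0.4),
                ns = runif(1, 0.3, 0.7)),
    HSIL = list(ell = runif(1, 1, 1.30), h = harm(4, 4, 12, 1.5, 3.5),
                no = notch(sample(1:3, 1), 4, 8, 0.15, 0.35),
                ns = runif(1, 0.5, 1.0))
  )
  shape_spec(base_radius = base, ellipticity = par$ell, harmonics = par$h,
             notches = par$no, noise_sigma = par$ns, seed = seed)
}

#' Generate a labeled synthetic cohort
#'
#' Reproducible three-class cohort: item seeds are drawn once from the
#' master seed, each item gets a class-specific random shape, a rasterized
#' mask and contour, and (optionally) a rendered image.
#'
#' @param n_per_class images per class.
#' @param master_seed master seed; the whole cohort is a deterministic
#'   function of it.
#' @param classes class labels to generate.
#' @param render if TRUE also render grayscale images (for the segmentation
#'   pipeline).
#' @param ... passed to [render_image()].
#' @return list with `items` (each: `id`, `class`, `seed`, `nucleus`, and
#'   optionally `image`) and `manifest` (data frame with one row per item).
#' @export
generate_cohort <- function(n_per_class = 200, master_seed = 1L,
                            classes = c("NILM", "LSIL", "HSIL"),
                            render = FALSE, ...) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  total <- n_per_class * length(classes)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  items <- vector("list", total)
  rows <- vector("list", total)
  i <- 0L
  for (cl in classes) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      sp <- random_shape_spec(cl, seed = seeds[i])
      nuc <- make_contour(sp)
      it <- list(id = sprintf("%s_%04d", cl, j), class = cl,
                 seed = seeds[i], nucleus = nuc)
      if (render) it$image <- render_image(nuc, seed = seeds[i], ...)$image
      items[[i]] <- it
      rows[[i]] <- data.frame(
        image_id = it$id, class = cl, seed = seeds[i],
        base_radius = sp$base_radius, ellipticity = sp$ellipticity,
        n_harmonics = if (is.null(sp$harmonics)) 0L else nrow(sp$harmonics),
        harmonic_amp = if (is.null(sp$harmonics)) 0 else sum(abs(sp$harmonics[, "amp"])),
        n_notches = if (is.null(sp$notches)) 0L else nrow(sp$notches),
        notch_depth = if (is.null(sp$notches)) 0 else sum(sp$notches[, "depth"]),
        noise_sigma = sp$noise_sigma
      )
    }
  }
  list(items = items, manifest = do.call(rbind, rows))
}
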