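#' Acquisition geometry for the 2D parallel-beam model
#'
#' Defines the image grid and the sinogram sampling used by every other
#' component: `n_pixels_x * n_pixels_y` square pixels of side `pixel_size`
#' (mm), centered on the origin, and `n_radial * n_angles` line-of-response
#' bins. Radial bin 1 is the most negative offset from the center of
#' rotation; angles live in `[0, pi)`.
#'
#' The number of detector measurements is `I = n_radial * n_angles` and the
#' image size is `J = n_pixels_x * n_pixels_y`.
#'
#' @param n_pixels_x,n_pixels_y Integer pixel counts of the image grid.
#' @param pixel_size Pixel side length in mm.
#' @param n_radial Number of radial bins per projection.
#' @param n_angles Number of projection angles.
#' @param radial_spacing Distance between adjacent radial bins in mm.
#'   Defaults to `pixel_size`.
#' @param angles Optional vector of strictly increasing angles in radians,
#'   all in `[0, pi)`. Defaults to `n_angles` equispaced angles starting
#'   at 0.
#' @return An object of class `pet_geometry`.
#' @examples
#' geom <- pet_geometry(32, 32, pixel_size = 2, n_radial = 48, n_angles = 60)
#' geom
#' @export
pet_geometry <- function(n_pixels_x, n_pixels_y, pixel_size,
                         n_radial, n_angles,
                         radial_spacing = pixel_size, angles = NULL) {
  stopifnot(length(n_pixels_x) == 1, length(n_pixels_y) == 1)
  n_pixels_x <- as.integer(n_pixels_x)
  n_pixels_y <- as.integer(n_pixels_y)
  n_radial <- as.integer(n_radial)
  n_angles <- as.integer(n_angles)
  if (any(c(n_pixels_x, n_pixels_y, n_radial, n_angles) < 1L))
    stop("invalid geometry: all grid counts must be >= 1", call. = FALSE)
  if (!(pixel_size > 0) || !(radial_spacing > 0))
    stop("invalid geometry: pixel_size and radial_spacing must be > 0",
         call. = FALSE)
  if (is.null(angles)) {
    angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  } else {
    if (length(angles) != n_angles)
      stop("angles must have length n_angles", call. = FALSE)
    if (any(!is.finite(angles)) || any(angles < 0) || any(angles >= pi))
      stop("angles must be finite and in [0, pi)", call. = FALSE)
    if (n_angles > 1L && any(diff(angles) <= 0))
      stop("angles must be strictly increasing", call. = FALSE)
  }
  structure(
    list(n_pixels_x = n_pixels_x, n_pixels_y = n_pixels_y,
         pixel_size = pixel_size, n_radial = n_radial,
         n_angles = n_angles, radial_spacing = radial_spacing,
         angles = as.numeric(angles)),
    class = "pet_geometry")
}

#' @export
print.pet_geometry <- function(x, ...) {
  cat(sprintf("pet_geometry: %d x %d image (%.3g mm pixels), %d radial bins x %d angles (%.3g mm spacing)\n",
              x$n_pixels_x, x$n_pixels_y, x$pixel_size,
              x$n_radial, x$n_angles, x$radial_spacing))
  invisible(x)
}

# Radial offsets (mm) of the bin centers, bin 1 most negative.
radial_offsets <- function(geom) {
  (seq_len(geom$n_radial) - (geom$n_radial + 1) / 2) * geom$radial_spacing
}

# Pixel-center coordinates (mm), origin at grid center, y increasing upward
# with image row 1 at the top.
pixel_centers <- function(geom) {
  xc <- (seq_len(geom$n_pixels_x) - (geom$n_pixels_x + 1) / 2) * geom$pixel_size
  yc <- ((geom$n_pixels_y + 1) / 2 - seq_len(geom$n_pixels_y)) * geom$pixel_size
  list(x = xc, y = yc)
}

geometry_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Activity image
#'
#' A non-negative 2D grid of radiotracer activity tied to a
#' [pet_geometry()]. Values are stored as a matrix with
#' `n_pixels_y` rows and `n_pixels_x` columns; vectorization (for the
#' system-matrix algebra) is column-major, R's native order.
#'
#' @param values Numeric matrix of non-negative, finite activities.
#' @param geometry A `pet_geometry`.
#' @return An object of class `pet_image`.
#' @export
activity_image <- function(values, geometry) {
  values <- as.matrix(values)
  if (!identical(dim(values),
                 c(geometry$n_pixels_y, geometry$n_pixels_x)))
    stop("image dimensions do not match geometry", call. = FALSE)
  if (any(!is.finite(values)))
    stop("activity image must be finite", call. = FALSE)
  if (any(values < 0))
    stop("activity image must be non-negative", call. = FALSE)
  structure(list(values = values, geometry = geometry), class = "pet_image")
}

#' Sinogram of event counts
#'
#' A non-negative `n_radial x n_angles` array of measured (or expected)
#' coincidence counts, tied to a [pet_geometry()].
#'
#' @param values Numeric matrix, `n_radial` rows by `n_angles` columns.
#' @param geometry A `pet_geometry`.
#' @return An object of class `pet_sinogram`.
#' @export
sinogram <- function(values, geometry) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(geometry$n_radial, geometry$n_angles)))
    stop("sinogram dimensions do not match geometry", call. = FALSE)
  if (any(!is.finite(values)))
    stop("sinogram must be finite", call. = FALSE)
  if (any(values < 0))
    stop("sinogram must be non-negative", call. = FALSE)
  structure(list(values = values, geometry = geometry),
            class = "pet_sinogram")
}

#' @export
print.pet_image <- function(x, ...) {
  cat(sprintf("pet_image: %d x %d, activity range [%.4g, %.4g], total %.6g\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              sum(x$values)))
  invisible(x)
}

#' @export
print.pet_sinogram <- function(x, ...) {
  cat(sprintf("pet_sinogram: %d radial x %d angles, total counts %.6g\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}
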