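#' @importFrom methods as is
#' @importFrom Matrix sparseMatrix colSums crossprod
NULL

# Trace one line of response through the pixel grid (Siddon-style).
# theta: projection angle in [0, pi); rho: signed radial offset (mm).
# Returns NULL for rays missing the field of view, otherwise a list with
# pixel rows, columns and intersection lengths (mm).
#
# A ray running exactly along an interior grid line splits its length
# half-and-half between the two adjacent pixel rows/columns, so symmetric
# geometries yield symmetric weights.
trace_ray <- function(theta, rho, nx, ny, p) {
  tol <- 1e-12
  ct <- cos(theta); st <- sin(theta)
  dx <- -st; dy <- ct                 # unit direction along the ray
  px <- rho * ct; py <- rho * st      # point of closest approach to origin
  xmin <- -nx * p / 2; xmax <- nx * p / 2
  ymin <- -ny * p / 2; ymax <- ny * p / 2

  # Axis-aligned rays lying exactly on an interior grid line: split.
  if (abs(dx) < tol) {
    k <- (px - xmin) / p
    if (abs(k - round(k)) < 1e-9) {
      k <- as.integer(round(k))
      if (k < 0L || k > nx) return(NULL)
      rows <- seq_len(ny)
      len <- rep(p, ny)
      if (k >= 1L && k <= nx - 1L) {       # interior vertical line
        return(list(row = rep(rows, 2L), col = rep(c(k, k + 1L), each = ny),
                    w = rep(len / 2, 2L)))
      }
      col <- if (k == 0L) 1L else nx       # grazing the outer edge
      return(list(row = rows, col = rep(col, ny), w = len))
    }
  }
  if (abs(dy) < tol) {
    k <- (ymax - py) / p
    if (abs(k - round(k)) < 1e-9) {
      k <- as.integer(round(k))
      if (k < 0L || k > ny) return(NULL)
      cols <- seq_len(nx)
      len <- rep(p, nx)
      if (k >= 1L && k <= ny - 1L) {       # interior horizontal line
        return(list(row = rep(c(k, k + 1L), each = nx), col = rep(cols, 2L),
                    w = rep(len / 2, 2L)))
      }
      row <- if (k == 0L) 1L else ny
      return(list(row = rep(row, nx), col = cols, w = len))
    }
  }

  # Parametric clipping against the bounding box.
  tlo <- -Inf; thi <- Inf
  if (abs(dx) > tol) {
    t1 <- (xmin - px) / dx; t2 <- (xmax - px) / dx
    tlo <- max(tlo, min(t1, t2)); thi <- min(thi, max(t1, t2))
  } else if (px < xmin || px > xmax) return(NULL)
  if (abs(dy) > tol) {
    t1 <- (ymin - py) / dy; t2 <- (ymax - py) / dy
    tlo <- max(tlo, min(t1, t2)); thi <- min(thi, max(t1, t2))
  } else if (py < ymin || py > ymax) return(NULL)
  if (!(thi > tlo + tol)) return(NULL)

  ts <- c(tlo, thi)
  if (abs(dx) > tol) ts <- c(ts, (xmin + (0:nx) * p - px) / dx)
  if (abs(dy) > tol) ts <- c(ts, (ymin + (0:ny) * p - py) / dy)
  ts <- ts[ts >= tlo & ts <= thi]
  ts <- sort(ts)
  len <- diff(ts)
  keep <- len > tol
  if (!any(keep)) return(NULL)
  tm <- (ts[-1L] + ts[-length(ts)])[keep] / 2
  len <- len[keep]
  xm <- px + tm * dx; ym <- py + tm * dy
  col <- floor((xm - xmin) / p) + 1
  row <- floor((ymax - ym) / p) + 1
  ok <- col >= 1 & col <= nx & row >= 1 & row <= ny
  if (!any(ok)) return(NULL)
  list(row = as.integer(row[ok]), col = as.integer(col[ok]), w = len[ok])
}

#' Build the sparse system matrix for a geometry
#'
#' Computes the `I x J` sparse matrix `A` of the idealized 2D parallel-beam
#' line-integral model, where entry `a_ij` is the intersection length (mm)
#' of line of response `i` with pixel `j`. The expected sinogram of an
#' activity image `x` is then `ybar_i = sum_j a_ij x_j`. Bins are ordered
#' radial-fastest (column-major over the sinogram array) and pixels
#' column-major over the image array.
#'
#' Rays that miss the field of view keep all-zero rows; downstream
#' algorithms skip zero-sensitivity bins rather than divide by zero. The
#' back projection used everywhere is the exact transpose of `A`, so the
#' gradient identities of the cross-entropy schemes hold to floating
#' point.
#'
#' @param geometry A [pet_geometry()].
#' @return An object of class `pet_system_matrix` with elements
#'   `geometry`, `entries` (a `dgCMatrix`), and `sensitivity`
#'   (`s_j = sum_i a_ij`, length `J`).
#' @examples
#' geom <- pet_geometry(16, 16, 2, n_radial = 24, n_angles = 24)
#' A <- build_system_matrix(geom)
#' range(A$sensitivity)
#' @export
build_system_matrix <- function(geometry) {
  stopifnot(inherits(geometry, "pet_geometry"))
  nx <- geometry$n_pixels_x; ny <- geometry$n_pixels_y
  p <- geometry$pixel_size
  offs <- radial_offsets(geometry)
  nr <- geometry$n_radial; na <- geometry$n_angles
  I <- nr * na; J <- nx * ny

  ii <- vector("list", I); jj <- vector("list", I); ww <- vector("list", I)
  idx <- 0L
  for (a in seq_len(na)) {
    theta <- geometry$angles[a]
    for (r in seq_len(nr)) {
      idx <- idx + 1L
      seg <- trace_ray(theta, offs[r], nx, ny, p)
      if (is.null(seg)) next
      ii[[idx]] <- rep.int(idx, length(seg$w))
      jj[[idx]] <- (seg$col - 1L) * ny + seg$row
      ww[[idx]] <- seg$w
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(I, J))
  structure(list(geometry = geometry, entries = A,
                 sensitivity = as.numeric(Matrix::colSums(A))),
            class = "pet_system_matrix")
}

#' @export
print.pet_system_matrix <- function(x, ...) {
  d <- dim(x$entries)
  cat(sprintf("pet_system_matrix: %d bins x %d pixels, %d nonzeros\n",
              d[1], d[2], length(x$entries@x)))
  invisible(x)
}

#' Forward project an activity image
#'
#' Applies the system matrix: `ybar_i = sum_j a_ij x_j`, the expected
#' (noise-free) sinogram of an activity image.
#'
#' @param A A [build_system_matrix()] result.
#' @param x A [activity_image()] on the same geometry.
#' @return A [sinogram()] of expected counts.
#' @export
forward_project <- function(A, x) {
  stopifnot(inherits(A, "pet_system_matrix"), inherits(x, "pet_image"))
  if (!geometry_equal(A$geometry, x$geometry))
    stop("image geometry does not match system matrix", call. = FALSE)
  y <- as.numeric(A$entries %*% as.vector(x$values))
  sinogram(matrix(y, nrow = A$geometry$n_radial), A$geometry)
}

#' Back project a sinogram
#'
#' Applies the exact transpose of the system matrix:
#' `z_j = sum_i a_ij y_i`. The pairing identity
#' `<A x, y> = <x, t(A) y>` holds to floating-point accuracy, which the
#' gradient-based reconstruction schemes rely on.
#'
#' @param A A [build_system_matrix()] result.
#' @param y A [sinogram()] on the same geometry.
#' @return A [activity_image()]-shaped object (non-negative if `y` is).
#' @export
back_project <- function(A, y) {
  stopifnot(inherits(A, "pet_system_matrix"), inherits(y, "pet_sinogram"))
  if (!geometry_equal(A$geometry, y$geometry))
    stop("sinogram geometry does not match system matrix", call. = FALSE)
  z <- as.numeric(Matrix::crossprod(A$entries, as.vector(y$values)))
  activity_image(matrix(z, nrow = A$geometry$n_pixels_y), A$geometry)
}
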