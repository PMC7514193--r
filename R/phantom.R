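#' Specification of the cylindrical rod phantom
#'
#' Describes a cylindrical body disk containing rows of hot cylindrical
#' rod inserts, one row per entry of `rod_diameters`. Rods in a row are
#' spaced at twice their diameter (center to center) and the rows are
#' spread vertically across the body. Rods are filled at
#' `rod_activity_ratio` times the background activity (hot-insert
#' convention: ratios quoted as "1:8" mean the insert is 8x background).
#'
#' @param body_diameter Body disk diameter in mm.
#' @param rod_diameters Rod diameters in mm, one row per diameter. May be
#'   empty for a uniform disk.
#' @param rods_per_row Number of rods per row.
#' @param rod_activity_ratio Rod-to-background activity ratio (> 0).
#' @param background_activity Background activity level (>= 0).
#' @param row_positions Optional vector of row center y-coordinates (mm);
#'   defaults to an even spread over 60% of the body diameter.
#' @return An object of class `rod_phantom_spec`.
#' @export
rod_phantom_spec <- function(body_diameter = 60,
                             rod_diameters = c(2, 3, 4, 5),
                             rods_per_row = 3,
                             rod_activity_ratio = 8,
                             background_activity = 1,
                             row_positions = NULL) {
  if (!(body_diameter > 0)) stop("body_diameter must be > 0", call. = FALSE)
  if (length(rod_diameters) && any(rod_diameters <= 0))
    stop("rod diameters must be > 0", call. = FALSE)
  if (!(rod_activity_ratio > 0))
    stop("rod_activity_ratio must be > 0", call. = FALSE)
  if (background_activity < 0)
    stop("background_activity must be >= 0", call. = FALSE)
  n_rows <- length(rod_diameters)
  if (is.null(row_positions)) {
    row_positions <- if (n_rows > 1L)
      seq(-0.3, 0.3, length.out = n_rows) * body_diameter
    else rep(0, n_rows)
  }
  if (length(row_positions) != n_rows)
    stop("row_positions must match rod_diameters in length", call. = FALSE)
  structure(list(body_diameter = body_diameter,
                 rod_diameters = as.numeric(rod_diameters),
                 rods_per_row = as.integer(rods_per_row),
                 rod_activity_ratio = rod_activity_ratio,
                 background_activity = background_activity,
                 row_positions = as.numeric(row_positions)),
            class = "rod_phantom_spec")
}

# Rod centers and diameters implied by a rod_phantom_spec.
rod_layout <- function(spec) {
  out <- list(cx = numeric(0), cy = numeric(0), d = numeric(0))
  for (k in seq_along(spec$rod_diameters)) {
    d <- spec$rod_diameters[k]
    n <- spec$rods_per_row
    cx <- (seq_len(n) - (n + 1) / 2) * 2 * d   # pitch = 2 diameters
    out$cx <- c(out$cx, cx)
    out$cy <- c(out$cy, rep(spec$row_positions[k], n))
    out$d <- c(out$d, rep(d, n))
  }
  out
}

validate_rod_layout <- function(spec) {
  lay <- rod_layout(spec)
  R <- spec$body_diameter / 2
  if (length(lay$d)) {
    if (any(sqrt(lay$cx^2 + lay$cy^2) + lay$d / 2 >= R))
      stop("rod phantom spec error: rods must lie strictly inside the body disk",
           call. = FALSE)
    n <- length(lay$d)
    if (n > 1L) {
      for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
        dist <- sqrt((lay$cx[a] - lay$cx[b])^2 + (lay$cy[a] - lay$cy[b])^2)
        if (dist < (lay$d[a] + lay$d[b]) / 2)
          stop("rod phantom spec error: rods overlap", call. = FALSE)
      }
    }
  }
  lay
}

#' Rasterize the rod phantom onto a geometry
#'
#' Pixels are assigned by center inclusion (no anti-aliasing): a pixel
#' belongs to the body disk or to a rod if its center does. Rod pixels get
#' `rod_activity_ratio * background_activity`; other in-body pixels get
#' `background_activity`; pixels outside the body are zero. Deterministic
#' for a fixed spec and geometry.
#'
#' @param spec A [rod_phantom_spec()].
#' @param geometry A [pet_geometry()].
#' @return A [activity_image()].
#' @examples
#' geom <- pet_geometry(64, 64, 1, n_radial = 64, n_angles = 60)
#' ph <- make_rod_phantom(rod_phantom_spec(body_diameter = 50), geom)
#' range(ph$values)
#' @export
make_rod_phantom <- function(spec, geometry) {
  stopifnot(inherits(spec, "rod_phantom_spec"),
            inherits(geometry, "pet_geometry"))
  lay <- validate_rod_layout(spec)
  ctr <- pixel_centers(geometry)
  X <- matrix(ctr$x, nrow = geometry$n_pixels_y,
              ncol = geometry$n_pixels_x, byrow = TRUE)
  Y <- matrix(ctr$y, nrow = geometry$n_pixels_y, ncol = geometry$n_pixels_x)
  R <- spec$body_diameter / 2
  img <- ifelse(X^2 + Y^2 <= R^2, spec$background_activity, 0)
  hot <- spec$rod_activity_ratio * spec$background_activity
  for (k in seq_along(lay$d)) {
    inside <- (X - lay$cx[k])^2 + (Y - lay$cy[k])^2 <= (lay$d[k] / 2)^2
    img[inside] <- hot
  }
  activity_image(img, geometry)
}

#' Specification of the lesion phantom
#'
#' A multi-ellipse background (painted in order, later ellipses on top)
#' with one circular lesion of known location. The lesion is filled at
#' `lesion_activity_ratio` times the background activity at its center.
#'
#' @param ellipses Data frame with columns `cx, cy, a, b, angle, activity`
#'   (mm, radians, activity units) describing the background anatomy.
#' @param lesion_center Length-2 numeric, lesion center (mm).
#' @param lesion_diameter Lesion diameter (mm).
#' @param lesion_activity_ratio Lesion-to-local-background ratio (> 0).
#' @return An object of class `lesion_phantom_spec`.
#' @export
lesion_phantom_spec <- function(ellipses = default_lesion_ellipses(),
                                lesion_center = c(6, 4),
                                lesion_diameter = 3,
                                lesion_activity_ratio = 5) {
  need <- c("cx", "cy", "a", "b", "angle", "activity")
  if (!all(need %in% names(ellipses)))
    stop("ellipses must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(ellipses$activity < 0))
    stop("ellipse activities must be >= 0", call. = FALSE)
  if (!(lesion_diameter > 0) || !(lesion_activity_ratio > 0))
    stop("lesion diameter and activity ratio must be > 0", call. = FALSE)
  structure(list(ellipses = as.data.frame(ellipses),
                 lesion_center = as.numeric(lesion_center),
                 lesion_diameter = lesion_diameter,
                 lesion_activity_ratio = lesion_activity_ratio),
            class = "lesion_phantom_spec")
}

#' Default elliptical background anatomy for the lesion phantom
#'
#' A body ellipse with two internal structures of differing uptake; a
#' synthetic stand-in for an anatomical atlas.
#' @return Data frame of ellipse parameters.
#' @export
default_lesion_ellipses <- function() {
  data.frame(
    cx = c(0, -8, 7),
    cy = c(0, 2, -6),
    a = c(26, 10, 8),
    b = c(20, 7, 5),
    angle = c(0, 0.4, -0.3),
    activity = c(1, 2, 1.5))
}

ellipse_mask <- function(X, Y, cx, cy, a, b, angle) {
  u <- cos(angle) * (X - cx) + sin(angle) * (Y - cy)
  v <- -sin(angle) * (X - cx) + cos(angle) * (Y - cy)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Rasterize the lesion phantom
#'
#' With `with_lesion = FALSE` returns the background-only anatomy; with
#' `with_lesion = TRUE` additionally paints the lesion disk. The two
#' outputs differ only inside the lesion support.
#'
#' @param spec A [lesion_phantom_spec()].
#' @param geometry A [pet_geometry()].
#' @param with_lesion Logical; paint the lesion?
#' @return A [activity_image()].
#' @export
make_lesion_phantom <- function(spec, geometry, with_lesion = TRUE) {
  stopifnot(inherits(spec, "lesion_phantom_spec"),
            inherits(geometry, "pet_geometry"))
  ctr <- pixel_centers(geometry)
  X <- matrix(ctr$x, nrow = geometry$n_pixels_y,
              ncol = geometry$n_pixels_x, byrow = TRUE)
  Y <- matrix(ctr$y, nrow = geometry$n_pixels_y, ncol = geometry$n_pixels_x)
  img <- matrix(0, geometry$n_pixels_y, geometry$n_pixels_x)
  es <- spec$ellipses
  for (k in seq_len(nrow(es))) {
    m <- ellipse_mask(X, Y, es$cx[k], es$cy[k], es$a[k], es$b[k], es$angle[k])
    img[m] <- es$activity[k]
  }
  if (with_lesion) {
    lc <- spec$lesion_center
    lm <- (X - lc[1])^2 + (Y - lc[2])^2 <= (spec$lesion_diameter / 2)^2
    # local background = value at the lesion center pixel
    ic <- which.min((X - lc[1])^2 + (Y - lc[2])^2)
    local_bg <- img[ic]
    if (local_bg <= 0)
      stop("lesion phantom spec error: lesion lies outside the body support",
           call. = FALSE)
    img[lm] <- spec$lesion_activity_ratio * local_bg
  }
  activity_image(img, geometry)
}
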