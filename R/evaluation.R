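# Evaluation instruments: contrast resolution between two rectangular
# ROIs, profile/surface extraction, and a channelized Hotelling observer
# (CHO) scored by the area under the ROC curve.

#' Rectangular region-of-interest pair
#'
#' Target and background rectangles given as inclusive 1-based pixel
#' index ranges. The regions must be non-empty, inside the image, and
#' disjoint.
#'
#' @param target,background Lists with integer vectors `rows` and `cols`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(target, background) {
  chk <- function(r, nm) {
    if (!is.list(r) || !all(c("rows", "cols") %in% names(r)))
      stop(nm, " must be a list with `rows` and `cols`", call. = FALSE)
    if (!length(r$rows) || !length(r$cols))
      stop(nm, " region is empty", call. = FALSE)
    list(rows = as.integer(r$rows), cols = as.integer(r$cols))
  }
  t <- chk(target, "target"); b <- chk(background, "background")
  tix <- as.vector(outer(t$rows, t$cols, function(r, c) paste(r, c)))
  bix <- as.vector(outer(b$rows, b$cols, function(r, c) paste(r, c)))
  if (length(intersect(tix, bix)))
    stop("target and background regions must be disjoint", call. = FALSE)
  structure(list(target = t, background = b), class = "roi_spec")
}

roi_mean <- function(values, r) mean(values[r$rows, r$cols])

#' Contrast resolution between two rectangles
#'
#' `CR = (mu_t - mu_b) / (mu_t + mu_b)` with `mu_t`, `mu_b` the mean
#' intensities of the target and background rectangles. Lies in
#' `[-1, 1]` for non-negative images, is invariant to global positive
#' scaling, and flips sign when the rectangles are swapped.
#'
#' @param image A [activity_image()].
#' @param roi A [roi_spec()].
#' @return Scalar CR.
#' @export
contrast_resolution <- function(image, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  v <- as_image_matrix(image)
  for (r in list(roi$target, roi$background)) {
    if (min(r$rows) < 1 || max(r$rows) > nrow(v) ||
        min(r$cols) < 1 || max(r$cols) > ncol(v))
      stop("ROI outside image bounds", call. = FALSE)
  }
  mt <- roi_mean(v, roi$target); mb <- roi_mean(v, roi$background)
  if (mt + mb == 0)
    stop("contrast resolution undefined: both region means are zero",
         call. = FALSE)
  (mt - mb) / (mt + mb)
}

#' Extract a line profile or rectangular surface patch
#'
#' With `from`/`to`, samples `n` points along the straight line between
#' two physical positions (mm, image-center origin) by bilinear
#' interpolation. With `rows`/`cols`, returns the rectangular patch of
#' pixel values (a "surface"). The maximum of the sampled values is
#' recorded in both cases.
#'
#' @param image A [activity_image()].
#' @param from,to Length-2 numeric positions `c(x, y)` in mm.
#' @param n Number of samples along the line.
#' @param rows,cols Integer index ranges for a patch.
#' @return List with `values`, `max`, and for line profiles `distance`
#'   (mm along the line).
#' @export
extract_profile <- function(image, from = NULL, to = NULL, n = 200,
                            rows = NULL, cols = NULL) {
  v <- as_image_matrix(image)
  if (!is.null(rows) || !is.null(cols)) {
    if (min(rows) < 1 || max(rows) > nrow(v) ||
        min(cols) < 1 || max(cols) > ncol(v))
      stop("patch outside image bounds", call. = FALSE)
    patch <- v[rows, cols, drop = FALSE]
    return(list(values = patch, max = max(patch)))
  }
  stopifnot(inherits(image, "pet_image"), length(from) == 2, length(to) == 2)
  geom <- image$geometry
  ctr <- pixel_centers(geom)
  tt <- seq(0, 1, length.out = n)
  xs <- from[1] + tt * (to[1] - from[1])
  ys <- from[2] + tt * (to[2] - from[2])
  # fractional array coordinates (row grows downward, y upward)
  fc <- (xs - ctr$x[1]) / geom$pixel_size + 1
  fr <- (ctr$y[1] - ys) / geom$pixel_size + 1
  if (any(fc < 1 - 1e-9) || any(fc > ncol(v) + 1e-9) ||
      any(fr < 1 - 1e-9) || any(fr > nrow(v) + 1e-9))
    stop("profile endpoints outside the pixel-center grid", call. = FALSE)
  fc <- pmin(pmax(fc, 1), ncol(v)); fr <- pmin(pmax(fr, 1), nrow(v))
  c0 <- pmin(floor(fc), ncol(v) - 1L); r0 <- pmin(floor(fr), nrow(v) - 1L)
  wc <- fc - c0; wr <- fr - r0
  val <- (1 - wr) * (1 - wc) * v[cbind(r0, c0)] +
    (1 - wr) * wc * v[cbind(r0, c0 + 1)] +
    wr * (1 - wc) * v[cbind(r0 + 1, c0)] +
    wr * wc * v[cbind(r0 + 1, c0 + 1)]
  list(values = val, max = max(val),
       distance = tt * sqrt(sum((to - from)^2)))
}

#' Rotationally symmetric difference-of-Gaussians channels
#'
#' Builds the spatial channel matrix `U` used by the channelized
#' Hotelling observer: `n_channels` octave-spaced radial
#' difference-of-Gaussians profiles evaluated on a square patch, each
#' column normalized to unit norm.
#'
#' @param patch_halfwidth Patch extends this many pixels either side of
#'   the lesion center (side `2*patch_halfwidth + 1`).
#' @param n_channels Number of channels (>= 2).
#' @param sigma0 Smallest Gaussian scale in pixels.
#' @return Matrix with one column per channel.
#' @export
cho_channels <- function(patch_halfwidth = 8, n_channels = 4, sigma0 = 1) {
  if (n_channels < 2) stop("need at least 2 channels", call. = FALSE)
  side <- 2L * patch_halfwidth + 1L
  g <- seq(-patch_halfwidth, patch_halfwidth)
  R2 <- outer(g, g, function(a, b) a^2 + b^2)
  sig <- sigma0 * 2^(0:n_channels)
  U <- sapply(seq_len(n_channels), function(j) {
    m <- exp(-R2 / (2 * sig[j + 1]^2)) - exp(-R2 / (2 * sig[j]^2))
    v <- as.vector(m)
    v / sqrt(sum(v^2))
  })
  dimnames(U) <- NULL
  U
}

#' Mann-Whitney AUC of two sets of statistics
#'
#' The proportion of (present, absent) pairs correctly ordered, counting
#' ties as 1/2 — the nonparametric area under the ROC curve,
#' `U / (n_pos * n_neg)`.
#'
#' @param t_present,t_absent Numeric test statistics of the two classes.
#' @return Scalar in `[0, 1]`.
#' @export
mann_whitney_auc <- function(t_present, t_absent) {
  cmp <- outer(t_present, t_absent, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) /
    (length(t_present) * length(t_absent))
}

#' Hotelling observer AUC from channel outputs
#'
#' Given channel-output matrices (channels x images) for the
#' signal-present and signal-absent classes, forms the Hotelling
#' template `w = S^-1 (vbar+ - vbar-)` with `S` the average within-class
#' covariance (optionally ridge-regularized), scores every image with
#' `t = w' v`, and returns the Mann-Whitney AUC. `method = "loo"`
#' retrains the template with the scored image left out.
#'
#' @param v_present,v_absent Numeric matrices, `K x n` channel outputs.
#' @param ridge Relative ridge added to `S` (times the mean diagonal);
#'   0 to require a well-conditioned covariance.
#' @param method `"resubstitution"` (default) or `"loo"`.
#' @return List with `auc`, `t_present`, `t_absent`, `template`, and
#'   the `method` used.
#' @export
hotelling_auc <- function(v_present, v_absent, ridge = 1e-6,
                          method = c("resubstitution", "loo")) {
  method <- method[1]
  v_present <- as.matrix(v_present); v_absent <- as.matrix(v_absent)
  if (nrow(v_present) != nrow(v_absent))
    stop("channel counts differ between classes", call. = FALSE)
  if (ncol(v_present) < 2 || ncol(v_absent) < 2)
    stop("need >= 2 images per class", call. = FALSE)

  template_for <- function(vp, va) {
    S <- (stats::cov(t(vp)) + stats::cov(t(va))) / 2
    if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), nrow(S))
    w <- tryCatch(solve(S, rowMeans(vp) - rowMeans(va)), error = function(e)
      stop("singular channel covariance; supply a positive `ridge` ",
           "(more images per class also helps): ", conditionMessage(e),
           call. = FALSE))
    w
  }

  if (method == "resubstitution") {
    w <- template_for(v_present, v_absent)
    tp <- as.numeric(crossprod(w, v_present))
    ta <- as.numeric(crossprod(w, v_absent))
  } else if (method == "loo") {
    tp <- vapply(seq_len(ncol(v_present)), function(i) {
      w <- template_for(v_present[, -i, drop = FALSE], v_absent)
      sum(w * v_present[, i])
    }, numeric(1))
    ta <- vapply(seq_len(ncol(v_absent)), function(i) {
      w <- template_for(v_present, v_absent[, -i, drop = FALSE])
      sum(w * v_absent[, i])
    }, numeric(1))
    w <- template_for(v_present, v_absent)
  } else stop("unknown method: ", method, call. = FALSE)

  list(auc = mann_whitney_auc(tp, ta), t_present = tp, t_absent = ta,
       template = w, method = method)
}

#' Channelized Hotelling observer on reconstructed images
#'
#' Channelizes a patch centered at the known lesion location in every
#' image, then applies [hotelling_auc()]. Both image lists must share a
#' geometry and have equal length.
#'
#' @param images_present,images_absent Lists of [activity_image()]s
#'   (signal-present / signal-absent reconstructions).
#' @param center Lesion center as `c(row, col)` pixel indices.
#' @param patch_halfwidth,n_channels,sigma0 Channel parameters, see
#'   [cho_channels()].
#' @param ridge,method Passed to [hotelling_auc()].
#' @return As [hotelling_auc()], plus the channel matrix `U`.
#' @export
cho_auc <- function(images_present, images_absent, center,
                    patch_halfwidth = 8, n_channels = 4, sigma0 = 1,
                    ridge = 1e-6, method = "resubstitution") {
  if (length(images_present) != length(images_absent))
    stop("need equally many signal-present and signal-absent images",
         call. = FALSE)
  if (length(images_present) < 2)
    stop("need >= 2 images per class", call. = FALSE)
  U <- cho_channels(patch_halfwidth, n_channels, sigma0)
  channelize <- function(imgs) {
    sapply(imgs, function(im) {
      v <- as_image_matrix(im)
      r <- (center[1] - patch_halfwidth):(center[1] + patch_halfwidth)
      c <- (center[2] - patch_halfwidth):(center[2] + patch_halfwidth)
      if (min(r) < 1 || max(r) > nrow(v) || min(c) < 1 || max(c) > ncol(v))
        stop("lesion patch outside image bounds", call. = FALSE)
      as.numeric(crossprod(U, as.vector(v[r, c])))
    })
  }
  out <- hotelling_auc(channelize(images_present),
                       channelize(images_absent),
                       ridge = ridge, method = method)
  out$U <- U
  out
}

#' Convert a physical position to the nearest pixel index
#'
#' @param geometry A [pet_geometry()].
#' @param xy Length-2 numeric `c(x, y)` in mm (image-center origin).
#' @return Integer `c(row, col)`.
#' @export
mm_to_pixel <- function(geometry, xy) {
  ctr <- pixel_centers(geometry)
  c(which.min(abs(ctr$y - xy[2])), which.min(abs(ctr$x - xy[1])))
}
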