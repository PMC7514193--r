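# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a Poisson sinogram realization at a target count level
#'
#' Forward projects the true activity, rescales the expected sinogram so
#' its total equals `target_counts`, then draws each bin independently
#' from a Poisson distribution with that expectation. Count levels are
#' specified as expected totals; the realized total fluctuates with
#' Poisson statistics around the target. Fully reproducible for a fixed
#' seed, and the caller's RNG state is left untouched.
#'
#' @param A A [build_system_matrix()] result.
#' @param x_true A non-negative [activity_image()] (the ground truth).
#' @param target_counts Expected total event count (> 0).
#' @param seed Integer random seed.
#' @return A [sinogram()] of integer counts. The scaled expectation is
#'   attached as attribute `"expected"`, and `seed`/`target_counts` as
#'   provenance attributes.
#' @examples
#' geom <- pet_geometry(24, 24, 2, n_radial = 32, n_angles = 30)
#' A <- build_system_matrix(geom)
#' ph <- make_rod_phantom(rod_phantom_spec(body_diameter = 40,
#'                                         rod_diameters = c(4, 6),
#'                                         rods_per_row = 2), geom)
#' y <- simulate_sinogram(A, ph, target_counts = 1e4, seed = 1)
#' sum(y$values)
#' @export
simulate_sinogram <- function(A, x_true, target_counts, seed) {
  stopifnot(inherits(A, "pet_system_matrix"), inherits(x_true, "pet_image"))
  if (!(target_counts > 0))
    stop("target_counts must be > 0", call. = FALSE)
  ybar <- forward_project(A, x_true)$values
  tot <- sum(ybar)
  if (tot <= 0)
    stop("cannot scale an all-zero expected sinogram to positive counts",
         call. = FALSE)
  ybar <- ybar * (target_counts / tot)
  counts <- with_seed(seed, stats::rpois(length(ybar), as.vector(ybar)))
  out <- sinogram(matrix(counts, nrow = nrow(ybar)), A$geometry)
  attr(out, "expected") <- ybar
  attr(out, "seed") <- as.integer(seed)
  attr(out, "target_counts") <- target_counts
  out
}
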