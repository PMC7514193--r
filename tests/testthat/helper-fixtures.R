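# Shared fixtures, built once per test run. All deterministic.

# Small, well-conditioned 16x16 acquisition used across reconstruction
# tests (enough angular sampling that EM converges cleanly).
fix_geom16 <- pet_geometry(16, 16, pixel_size = 2, n_radial = 24,
                           n_angles = 24)
fix_A16 <- build_system_matrix(fix_geom16)
fix_rod16 <- make_rod_phantom(
  rod_phantom_spec(body_diameter = 30, rod_diameters = c(4, 5),
                   rods_per_row = 2),
  fix_geom16)

# A tiny deterministic filter bank with zero-mean kernels.
fix_bank3 <- local({
  set.seed(421)
  filter_bank(lapply(1:3, function(k) {
    m <- matrix(rnorm(25), 5, 5)
    m - mean(m)
  }), alphas = c(0.7, 1.3, 2.1))
})

# Independent geometric oracle: length of the intersection of the ray
# (angle theta, radial offset rho) with the centered square of side W,
# by Liang-Barsky style parametric clipping. Used to check system-matrix
# row sums without going through the package's ray tracer.
oracle_ray_box_chord <- function(theta, rho, W) {
  d <- c(-sin(theta), cos(theta))
  p0 <- rho * c(cos(theta), sin(theta))
  tlo <- -Inf; thi <- Inf
  for (ax in 1:2) {
    if (abs(d[ax]) > 1e-14) {
      t1 <- (-W / 2 - p0[ax]) / d[ax]
      t2 <- (W / 2 - p0[ax]) / d[ax]
      tlo <- max(tlo, min(t1, t2)); thi <- min(thi, max(t1, t2))
    } else if (abs(p0[ax]) > W / 2) return(0)
  }
  max(0, thi - tlo)
}

# Random positive EM test problem on the 16x16 fixture.
random_em_problem <- function(seed) {
  set.seed(seed)
  x <- matrix(runif(16 * 16, 0.1, 4), 16, 16)
  x[fix_A16$sensitivity == 0] <- 0
  y <- simulate_sinogram(fix_A16, activity_image(fix_rod16$values, fix_geom16),
                         target_counts = 2e4, seed = seed)
  list(x = activity_image(x, fix_geom16), y = y)
}

expect_rel_equal <- function(a, b, tol, scale = max(abs(b), 1e-300)) {
  expect_lt(max(abs(a - b)) / scale, tol)
}
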