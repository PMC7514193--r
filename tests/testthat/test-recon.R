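test_that("cross-entropy satisfies the KL identities", {
  set.seed(41)
  v <- runif(30, 0, 5)
  expect_equal(cross_entropy(v, v), 0)
  expect_equal(cross_entropy(0, 2), 2)
  expect_equal(cross_entropy(c(0, 0), c(1.5, 2.5)), 4)
  expect_true(is.infinite(cross_entropy(c(1, 0), c(0, 1))))
  expect_error(cross_entropy(c(-1, 1), c(1, 1)), "non-negative")

  # term-by-term independent summation
  y <- runif(50, 0.01, 8); b <- runif(50, 0.01, 8)
  manual <- 0
  for (i in seq_along(y))
    manual <- manual + y[i] * log(y[i]) - y[i] * log(b[i]) - y[i] + b[i]
  expect_equal(cross_entropy(y, b), manual, tolerance = 1e-12)
  expect_gte(cross_entropy(y, b), 0)
})

test_that("EM has the exact fixed-point and scalar closed-form behavior", {
  # noiseless consistent data: the truth is a fixed point
  yb <- forward_project(fix_A16, fix_rod16)
  x1 <- em_step(fix_rod16, yb, fix_A16)
  expect_rel_equal(x1$values, fix_rod16$values, 1e-12)

  # 1x1 system with a = 2, y = 6, x = 1: one step lands on y/a = 3
  g1 <- pet_geometry(1, 1, pixel_size = 2, n_radial = 1, n_angles = 1,
                     angles = 0)
  A1 <- build_system_matrix(g1)
  expect_equal(as.numeric(A1$entries), 2)
  x <- em_step(activity_image(matrix(1, 1, 1), g1),
               sinogram(matrix(6, 1, 1), g1), A1)
  expect_equal(as.numeric(x$values), 3)
})

test_that("log-likelihood is non-decreasing along an EM run", {
  g <- pet_geometry(8, 8, 3, n_radial = 12, n_angles = 12)
  A <- build_system_matrix(g)
  truth <- make_rod_phantom(rod_phantom_spec(body_diameter = 20,
                                             rod_diameters = 6,
                                             rods_per_row = 1,
                                             row_positions = 0), g)
  y <- simulate_sinogram(A, truth, 5e3, seed = 8)
  x <- activity_image(matrix(ifelse(A$sensitivity > 0, 1, 0), 8, 8), g)
  ll <- numeric(50)
  for (i in 1:50) {
    x <- em_step(x, y, A)
    ll[i] <- poisson_loglik(y$values, forward_project(A, x)$values)
  }
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-1])))
})

test_that("the MXE gradient step is algebraically the EM step", {
  for (s in 1:10) {
    pr <- random_em_problem(200 + s)
    xe <- em_step(pr$x, pr$y, fix_A16)
    xm <- mxe1_step(pr$x, pr$y, fix_A16)
    expect_rel_equal(xm$values, xe$values, 1e-12,
                     scale = max(xe$values))
  }
})

test_that("a zero cross-entropy gradient leaves the iterate unchanged", {
  yb <- forward_project(fix_A16, fix_rod16)
  x1 <- mxe1_step(fix_rod16, yb, fix_A16)
  expect_rel_equal(x1$values, fix_rod16$values, 1e-12)
})

test_that("cross-entropy decreases along an MXE run", {
  pr <- random_em_problem(77)
  x <- pr$x
  d <- numeric(30)
  for (i in 1:30) {
    x <- mxe1_step(x, pr$y, fix_A16)
    d[i] <- cross_entropy(pr$y$values, forward_project(fix_A16, x)$values)
  }
  expect_true(all(diff(d) <= 1e-8 * abs(d[-1])))
})

test_that("one EM step conserves projected counts", {
  for (s in 1:5) {
    pr <- random_em_problem(300 + s)
    x0 <- activity_image(
      matrix(ifelse(fix_A16$sensitivity > 0, 0.5, 0), 16, 16), fix_geom16)
    x1 <- em_step(x0, pr$y, fix_A16)
    q <- as.numeric(fix_A16$entries %*% as.vector(x0$values))
    live_counts <- sum(pr$y$values[matrix(q > 0, nrow = 24)])
    expect_rel_equal(sum(fix_A16$sensitivity * as.vector(x1$values)),
                     live_counts, 1e-8, scale = live_counts)
  }
})

test_that("the regularized step reduces to EM when beta is zero", {
  pr <- random_em_problem(55)
  xe <- em_step(pr$x, pr$y, fix_A16)
  xf <- mxe_foe_step(pr$x, pr$y, fix_A16, fix_bank3, beta = 0)
  expect_rel_equal(xf$values, xe$values, 1e-12, scale = max(xe$values))
})

test_that("uniform image + consistent data is a fixed point of the regularized step", {
  # flat truth restricted to the fully-sensitive interior
  g <- fix_geom16
  flat <- activity_image(
    matrix(ifelse(fix_A16$sensitivity > 0, 2, 0), 16, 16), g)
  yb <- forward_project(fix_A16, flat)
  x1 <- mxe_foe_step(flat, yb, fix_A16, fix_bank3, beta = 0.5)
  # fidelity gradient vanishes; FoE gradient vanishes only where the
  # filter windows see constant activity (interior away from the
  # zero-sensitivity corners)
  interior <- matrix(FALSE, 16, 16); interior[7:10, 7:10] <- TRUE
  expect_rel_equal(x1$values[interior], flat$values[interior], 1e-9,
                   scale = 2)
})

test_that("the non-negativity safeguard clamps, backtracks, and never increases the objective", {
  g <- fix_geom16
  x_prev <- activity_image(matrix(1, 16, 16), g)
  obj <- function(m) sum((m - 0.8)^2)

  # plain decrease, no negatives: returned unchanged
  prop <- matrix(0.9, 16, 16)
  out <- nonneg_safeguard(x_prev, prop, obj)
  expect_equal(out$values, prop)
  expect_equal(attr(out, "clips"), 0)

  # one negative entry, still decreasing after the clamp
  prop2 <- matrix(0.9, 16, 16); prop2[3, 3] <- -0.05
  out2 <- nonneg_safeguard(x_prev, prop2, obj)
  expect_equal(out2$values[3, 3], 0)
  expect_equal(out2$values[-(3 + 2 * 16)], prop2[-(3 + 2 * 16)])
  expect_equal(attr(out2, "clips"), 1)

  # adversarial proposal that increases the objective: result never worse
  prop3 <- matrix(5, 16, 16)
  out3 <- nonneg_safeguard(x_prev, prop3, obj)
  expect_lte(obj(out3$values), obj(x_prev$values))
})

test_that("the relative-difference penalty gradient is exact and reduces to EM when off", {
  set.seed(61)
  x <- matrix(runif(64, 0.2, 3), 8, 8)
  g <- cp_penalty_gradient(x, gamma = 0.1)
  h <- 1e-6
  fd <- matrix(0, 8, 8)
  for (i in 1:64) {
    e <- matrix(0, 8, 8); e[i] <- h
    fd[i] <- (cp_penalty(x + e, 0.1) - cp_penalty(x - e, 0.1)) / (2 * h)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)

  # uniform image: zero penalty, zero gradient
  expect_equal(cp_penalty(matrix(2, 8, 8)), 0)
  expect_equal(max(abs(cp_penalty_gradient(matrix(2, 8, 8)))), 0)

  pr <- random_em_problem(62)
  xe <- em_step(pr$x, pr$y, fix_A16)
  xc0 <- cp_step(pr$x, pr$y, fix_A16, cp_beta = 0)
  expect_rel_equal(xc0$values, xe$values, 1e-12, scale = max(xe$values))
  flat <- activity_image(matrix(ifelse(fix_A16$sensitivity > 0, 1, 0),
                                16, 16), fix_geom16)
  xcf <- cp_step(flat, pr$y, fix_A16, cp_beta = 0.01)
  xef <- em_step(flat, pr$y, fix_A16)
  expect_rel_equal(xcf$values, xef$values, 1e-10, scale = max(xef$values))
})

test_that("reconstruct records traces, clip counts and configuration echoes", {
  pr <- random_em_problem(71)
  fe <- reconstruct(pr$y, fix_A16, recon_config("EM"))
  expect_length(fe$objective_trace, 12)
  expect_true(all(diff(fe$objective_trace) >= -1e-8 * abs(fe$objective_trace[-1])))
  expect_true(all(fe$image$values >= 0))

  ff <- reconstruct(pr$y, fix_A16,
                    recon_config("MXE_FOE", filter_bank = fix_bank3))
  expect_length(ff$objective_trace, 27)
  expect_equal(ff$config$beta, 0.5)
  expect_length(ff$negativity_clips, 27)
  expect_true(all(diff(ff$objective_trace) <= 1e-9 * abs(ff$objective_trace[-1])))

  fc <- reconstruct(pr$y, fix_A16, recon_config("CP"))
  expect_equal(fc$config$cp_beta, 0.01)
  expect_equal(fc$config$cp_gamma, 0.1)
  expect_equal(fc$config$cp_lambda, 0.97)
  expect_true(all(fc$image$values >= 0))

  expect_error(recon_config("NOT_AN_ALGO"), "arg")
  # deterministic rerun
  fe2 <- reconstruct(pr$y, fix_A16, recon_config("EM"))
  expect_identical(fe$image$values, fe2$image$values)
})

test_that("500 EM iterations recover a noiseless well-sampled phantom", {
  g <- pet_geometry(16, 16, pixel_size = 2, n_radial = 24, n_angles = 48)
  A <- build_system_matrix(g)
  truth <- make_rod_phantom(rod_phantom_spec(body_diameter = 30,
                                             rod_diameters = c(4, 5),
                                             rods_per_row = 2), g)
  yb <- forward_project(A, truth)
  fit <- reconstruct(yb, A, recon_config("EM", n_iterations = 500))
  nrmse <- sqrt(mean((fit$image$values - truth$values)^2)) /
    sqrt(mean(truth$values^2))
  expect_lt(nrmse, 0.01)
})
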