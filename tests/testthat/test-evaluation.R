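test_that("contrast resolution follows the two-ROI mean contrast", {
  g <- pet_geometry(16, 16, 1, n_radial = 16, n_angles = 8)
  v <- matrix(1, 16, 16)
  v[3:5, 3:5] <- 3
  img <- activity_image(v, g)
  roi <- roi_spec(target = list(rows = 3:5, cols = 3:5),
                  background = list(rows = 10:12, cols = 10:12))
  expect_equal(contrast_resolution(img, roi), 0.5)

  # equal means -> 0; empty background -> 1
  v2 <- matrix(2, 16, 16)
  expect_equal(contrast_resolution(activity_image(v2, g), roi), 0)
  v3 <- matrix(0, 16, 16); v3[3:5, 3:5] <- 4
  expect_equal(contrast_resolution(activity_image(v3, g), roi), 1)

  # invariant to positive rescaling; antisymmetric under ROI swap
  expect_equal(contrast_resolution(activity_image(7 * v, g), roi),
               contrast_resolution(img, roi))
  swapped <- roi_spec(target = roi$background, background = roi$target)
  expect_equal(contrast_resolution(img, swapped),
               -contrast_resolution(img, roi))

  expect_error(contrast_resolution(activity_image(matrix(0, 16, 16), g), roi),
               "undefined")
  expect_error(roi_spec(target = list(rows = 1:2, cols = 1:2),
                        background = list(rows = 2:3, cols = 2:3)),
               "disjoint")
  expect_error(contrast_resolution(img,
      roi_spec(target = list(rows = 15:17, cols = 1:2),
               background = list(rows = 1:2, cols = 1:2))),
    "bounds")
})

test_that("profiles sample uniform disks and hot rods faithfully", {
  g <- pet_geometry(32, 32, 1, n_radial = 32, n_angles = 8)
  ph <- make_rod_phantom(rod_phantom_spec(body_diameter = 28,
                                          rod_diameters = numeric(0),
                                          background_activity = 2), g)
  pr <- extract_profile(ph, from = c(-8, 0), to = c(8, 0), n = 50)
  expect_true(all(pr$values == 2))
  expect_equal(pr$max, 2)

  hot <- make_rod_phantom(rod_phantom_spec(body_diameter = 28,
                                           rod_diameters = 6,
                                           rods_per_row = 1,
                                           row_positions = 0,
                                           rod_activity_ratio = 8), g)
  pr2 <- extract_profile(hot, from = c(-10, 0), to = c(10, 0), n = 201)
  expect_equal(pr2$max, 8)

  # patch extraction records its maximum
  sf <- extract_profile(hot, rows = 10:20, cols = 10:20)
  expect_equal(dim(sf$values), c(11, 11))
  expect_equal(sf$max, max(hot$values[10:20, 10:20]))
  expect_error(extract_profile(hot, rows = 30:35, cols = 1:2), "bounds")
})

test_that("bilinear sampling reproduces a linear ramp exactly", {
  g <- pet_geometry(32, 32, 1, n_radial = 32, n_angles = 8)
  ctrx <- (seq_len(32) - 16.5)
  ramp <- activity_image(
    matrix(rep(ctrx + 20, each = 32), 32, 32), g)   # value = x + 20
  pr <- extract_profile(ramp, from = c(-10.3, -4.2), to = c(11.7, 6.9),
                        n = 97)
  xs <- seq(-10.3, 11.7, length.out = 97)
  expect_lt(max(abs(pr$values - (xs + 20))), 1e-10)
})

test_that("Mann-Whitney AUC obeys its identities", {
  tp <- c(3, 5, 7); tn <- c(1, 2, 6)
  # direct pair count: 7 of the 9 (present, absent) pairs are ordered
  # correctly (3 and 5 both lose to 6), no ties
  expect_equal(mann_whitney_auc(tp, tn), 7 / 9)
  expect_equal(mann_whitney_auc(tn, tp), 1 - 7 / 9)
  expect_equal(mann_whitney_auc(c(1, 1), c(1, 1)), 0.5)
  # invariance under strictly increasing transforms
  expect_equal(mann_whitney_auc(exp(tp), exp(tn)),
               mann_whitney_auc(tp, tn))
})

test_that("the Hotelling observer hits the degenerate anchors", {
  g <- pet_geometry(24, 24, 1, n_radial = 24, n_angles = 8)
  set.seed(91)
  mk <- function(shift) {
    v <- matrix(runif(576), 24, 24)
    v[11:13, 11:13] <- v[11:13, 11:13] + shift
    activity_image(v, g)
  }
  # the two classes identical image-for-image: all statistics tie
  same <- lapply(1:6, function(i) mk(0))
  expect_equal(cho_auc(same, same, center = c(12, 12),
                       patch_halfwidth = 5)$auc, 0.5)

  # huge separation: perfect discrimination
  hi <- lapply(1:6, function(i) mk(50))
  lo <- lapply(1:6, function(i) mk(0))
  expect_equal(cho_auc(hi, lo, center = c(12, 12),
                       patch_halfwidth = 5)$auc, 1)

  expect_error(cho_auc(hi, lo[1:3], center = c(12, 12)), "equally many")
  expect_error(cho_auc(hi[1], lo[1], center = c(12, 12)), ">= 2")
})

test_that("AUC matches the multivariate-normal closed form", {
  # Gaussian channel outputs with known means and covariance: the ideal
  # linear observer attains AUC = Phi(d_A / sqrt(2)).
  K <- 4
  set.seed(92)
  Sig <- crossprod(matrix(rnorm(K * K), K)) / K + diag(K)
  mu <- c(0.9, -0.4, 0.5, 0.2)
  dA <- sqrt(drop(t(mu) %*% solve(Sig, mu)))
  target <- pnorm(dA / sqrt(2))
  L <- chol(Sig)
  draw_auc <- function(n) replicate(200, {
    vp <- t(L) %*% matrix(rnorm(K * n), K) + mu
    va <- t(L) %*% matrix(rnorm(K * n), K)
    hotelling_auc(vp, va, ridge = 1e-8)$auc
  })
  # estimating the template from the scored sample is optimistic by
  # O(K/n); at n = 150 per class the residual sits inside a 0.02 band
  a150 <- draw_auc(150)
  expect_lt(abs(mean(a150) - target), 0.02)
  # and the optimism shrinks with the training-sample size
  a25 <- draw_auc(25)
  expect_lt(abs(mean(a150) - target), abs(mean(a25) - target))
})

test_that("AUC does not decrease with channel-output separation", {
  K <- 3
  set.seed(93)
  noise_p <- matrix(rnorm(K * 25), K)
  noise_a <- matrix(rnorm(K * 25), K)
  mu <- c(1, 0.5, -0.2)
  aucs <- vapply(c(0.2, 0.6, 1.2, 2.5), function(scale) {
    hotelling_auc(noise_p + mu * scale, noise_a, ridge = 1e-8)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
  expect_true(all(aucs >= 0 & aucs <= 1))
})

test_that("singular covariance without a ridge surfaces a helpful error", {
  vp <- matrix(1, 3, 5) + rbind(1:5, 1:5, 1:5) * 0   # rank-deficient
  va <- vp
  expect_error(hotelling_auc(vp, va, ridge = 0), "ridge")
})

test_that("leave-one-out scoring is available and bounded", {
  set.seed(94)
  vp <- matrix(rnorm(4 * 10, mean = 0.8), 4)
  va <- matrix(rnorm(4 * 10), 4)
  res <- hotelling_auc(vp, va, method = "loo")
  expect_equal(res$method, "loo")
  expect_gte(res$auc, 0); expect_lte(res$auc, 1)
})
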