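test_that("Student-t expert and influence function behave as stated", {
  for (a in c(0.3, 1, 2.5)) expect_equal(expert_value(0, a), 1)
  expect_equal(expert_value(sqrt(2), 1), 0.5)
  expect_equal(expert_value(3, 2.5), exp(-2.5 * log(1 + 4.5)),
               tolerance = 1e-14)
  expect_error(expert_value(1, 0), "positive")
  expect_error(expert_influence(1, -2), "positive")

  # psi is odd and bounded by alpha/sqrt(2) (maximum at z = sqrt(2))
  z <- seq(-50, 50, by = 0.001)
  for (a in c(0.4, 1, 3.7)) {
    psi <- expert_influence(z, a)
    expect_equal(psi, -rev(psi))
    expect_lte(max(abs(psi)), a / sqrt(2) + 1e-12)
    expect_equal(max(abs(psi)), abs(expert_influence(sqrt(2), a)),
                 tolerance = 1e-6)
  }
})

test_that("filter bank stores mirrored kernels; mirroring is an involution", {
  b <- fix_bank3
  for (k in 1:3) {
    expect_equal(b$mirrored[[k]], b$filters[[k]][5:1, 5:1])
    expect_equal(b$mirrored[[k]][5:1, 5:1], b$filters[[k]])
  }
  expect_error(filter_bank(b$filters, c(1, 1, 0)), "positive")
  expect_error(filter_bank(list(matrix(1, 5, 5), matrix(1, 3, 3)), c(1, 1)),
               "share one size")
})

test_that("energy is zero for constant images under zero-mean kernels", {
  x <- matrix(4.2, 12, 12)
  e <- foe_energy(x, fix_bank3)
  expect_lt(e$value, 1e-20)
  expect_equal(e$value, sum(e$per_expert))
})

test_that("energy is linear in alpha and matches a nested-loop oracle", {
  set.seed(31)
  x <- matrix(runif(144, 0, 3), 12, 12)
  e1 <- foe_energy(x, fix_bank3)
  b2 <- filter_bank(fix_bank3$filters, 2 * fix_bank3$alphas)
  expect_equal(foe_energy(x, b2)$per_expert, 2 * e1$per_expert)

  oracle <- 0
  for (k in 1:3) {
    J <- fix_bank3$filters[[k]]
    for (p in 1:8) for (q in 1:8) {
      z <- sum(J * x[p:(p + 4), q:(q + 4)])
      oracle <- oracle - fix_bank3$alphas[k] * log((1 + z^2 / 2)^-1)
    }
  }
  expect_equal(e1$value, oracle, tolerance = 1e-12)
})

test_that("images smaller than the kernel are rejected", {
  expect_error(foe_energy(matrix(1, 4, 4), fix_bank3), "smaller")
  expect_error(foe_gradient(matrix(1, 3, 5), fix_bank3), "smaller")
})

test_that("gradient matches central finite differences of the energy", {
  set.seed(32)
  x <- matrix(runif(100, 0.2, 2.5), 10, 10)
  g <- foe_gradient(x, fix_bank3)
  h <- 1e-5
  fd <- matrix(0, 10, 10)
  for (i in seq_len(100)) {
    e <- matrix(0, 10, 10); e[i] <- h
    fd[i] <- (foe_energy(x + e, fix_bank3)$value -
                foe_energy(x - e, fix_bank3)$value) / (2 * h)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)

  # constant image, zero-mean kernels: exactly stationary
  expect_equal(max(abs(foe_gradient(matrix(2, 10, 10), fix_bank3))), 0)
})

test_that("an impulse filter reduces the gradient to the pointwise influence", {
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  b <- filter_bank(list(imp), alphas = 1)
  set.seed(33)
  x <- matrix(runif(100, 0, 4), 10, 10)
  g <- foe_gradient(x, b)
  interior <- x[3:8, 3:8]
  expect_equal(g[3:8, 3:8], interior / (1 + interior^2 / 2),
               tolerance = 1e-12)
  # outside the valid region the energy does not see those pixels... but
  # border pixels still receive scattered contributions only from valid
  # windows; corners beyond reach stay zero
  expect_equal(g[1, 1], 0)
})

test_that("energy is translation covariant on the shared valid region", {
  set.seed(34)
  x <- matrix(runif(15 * 15, 0, 2), 15, 15)
  xs <- x[2:15, 2:15]                      # shifted view
  e_full <- foe_energy(x[2:15, 2:15], fix_bank3)$value
  e_view <- foe_energy(xs, fix_bank3)$value
  expect_identical(e_full, e_view)
})

test_that("contrastive divergence training honors its contracts", {
  imgs <- synthetic_training_images(n = 6, size = 32, seed = 3)
  b <- train_filters_cd(imgs, K = 4, n_patches = 800, n_iter = 60,
                        batch_size = 200, seed = 1)
  expect_length(b$filters, 4)
  expect_true(all(abs(vapply(b$filters, mean, numeric(1))) < 1e-8))
  expect_true(all(is.finite(unlist(b$filters))))
  expect_true(all(is.finite(b$alphas)) && all(b$alphas > 0))

  b2 <- train_filters_cd(imgs, K = 4, n_patches = 800, n_iter = 60,
                         batch_size = 200, seed = 1)
  expect_identical(lapply(b$filters, c), lapply(b2$filters, c))
  expect_identical(b$alphas, b2$alphas)

  expect_error(train_filters_cd(list(matrix(1, 20, 20)), K = 2,
                                n_patches = 200, n_iter = 10),
               "degenerate")
})

test_that("a smooth-trained model assigns smooth held-out patches less energy", {
  smooth <- lapply(1:6, function(i) {
    outer(sin(seq(0, 3, length.out = 40) + i),
          cos(seq(0, 2, length.out = 40))) + 2
  })
  noisy <- lapply(1:6, function(i) {
    set.seed(100 + i); matrix(runif(1600, 0, 2), 40, 40)
  })
  bs <- train_filters_cd(smooth, K = 4, n_patches = 1200, n_iter = 100,
                         batch_size = 300, seed = 2)
  bn <- train_filters_cd(noisy, K = 4, n_patches = 1200, n_iter = 100,
                         batch_size = 300, seed = 2)
  held <- lapply(7:9, function(i) {
    outer(sin(seq(0, 3, length.out = 40) + i),
          cos(seq(0, 2, length.out = 40))) + 2
  })
  e_smooth <- mean(vapply(held, function(m) foe_energy(m, bs)$value,
                          numeric(1)))
  e_noise <- mean(vapply(held, function(m) foe_energy(m, bn)$value,
                         numeric(1)))
  expect_lt(e_smooth, e_noise)
})

test_that("filter bank files round-trip losslessly and validate", {
  path <- withr::local_tempfile(fileext = ".json")
  bank <- fix_bank3
  bank$provenance <- list(note = "fixture")
  write_filter_bank(bank, path)
  back <- read_filter_bank(path)
  expect_identical(lapply(back$filters, c), lapply(bank$filters, c))
  expect_identical(back$alphas, bank$alphas)
  expect_equal(back$provenance$note, "fixture")

  # alpha <= 0 on disk is a parameter error
  txt <- jsonlite::read_json(path)
  txt$alphas[[2]] <- -1
  jsonlite::write_json(txt, path, auto_unbox = TRUE)
  expect_error(read_filter_bank(path), "positive")
  writeLines("{\"format\": \"something_else\"}", path)
  expect_error(read_filter_bank(path), "format")
})

test_that("the shipped default bank matches its advertised layout", {
  b <- default_filter_bank()
  expect_length(b$filters, 24)
  expect_true(all(vapply(b$filters, function(f) identical(dim(f), c(5L, 5L)),
                         logical(1))))
  expect_true(all(abs(vapply(b$filters, mean, numeric(1))) < 1e-8))
  expect_true(all(b$alphas > 0))
  expect_equal(sum(b$alphas), 4, tolerance = 1e-12)
})

test_that("rescaling a bank pins the total expert weight", {
  b <- rescale_filter_bank(fix_bank3, alpha_total = 2)
  expect_equal(sum(b$alphas), 2)
  expect_equal(b$alphas / sum(b$alphas),
               fix_bank3$alphas / sum(fix_bank3$alphas))
})
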