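# Field-of-Experts image prior: K learned linear filters J^(k) with
# Student-t expert potentials phi(z, alpha) = (1 + z^2/2)^(-alpha).
# The (unnormalized) prior of an image x is
#   P(x) ~ prod_k prod_p phi((J^(k) . x)_p, alpha_k)
# over all fully-interior ("valid") filter positions p, and the energy is
# its negative log, E(x) = sum_k sum_p alpha_k log(1 + z_kp^2 / 2).
# The partition function is never computed; it cancels in all gradients.

#' Construct a filter bank
#'
#' Bundles `K` linear expert filters (typically 5x5, as trained) with
#' their per-expert Student-t shape parameters `alpha_k`. Each kernel's
#' 180-degree rotation (the "mirrored" kernel that appears in the prior
#' gradient) is stored alongside it.
#'
#' @param filters List of `K` numeric matrices, all the same (odd) size.
#' @param alphas Numeric vector of `K` positive shape parameters.
#' @param provenance Optional named list recording how the bank was
#'   trained; carried through file round-trips.
#' @return An object of class `foe_filter_bank`.
#' @export
filter_bank <- function(filters, alphas, provenance = list()) {
  if (!length(filters)) stop("need at least one filter", call. = FALSE)
  filters <- lapply(filters, as.matrix)
  d <- dim(filters[[1]])
  if (!all(vapply(filters, function(f) identical(dim(f), d), logical(1))))
    stop("all filters must share one size", call. = FALSE)
  if (!all(vapply(filters, function(f) all(is.finite(f)), logical(1))))
    stop("filters must be finite", call. = FALSE)
  if (length(alphas) != length(filters))
    stop("alphas must match filters in length", call. = FALSE)
  if (any(!is.finite(alphas)) || any(alphas <= 0))
    stop("expert shape parameters alpha must be positive", call. = FALSE)
  structure(list(filters = filters,
                 mirrored = lapply(filters, rot180),
                 alphas = as.numeric(alphas),
                 provenance = provenance),
            class = "foe_filter_bank")
}

rot180 <- function(k) k[nrow(k):1, ncol(k):1, drop = FALSE]

#' @export
print.foe_filter_bank <- function(x, ...) {
  d <- dim(x$filters[[1]])
  cat(sprintf("foe_filter_bank: K = %d filters of %d x %d, alpha in [%.3g, %.3g]\n",
              length(x$filters), d[1], d[2], min(x$alphas), max(x$alphas)))
  invisible(x)
}

#' Student-t expert potential
#'
#' `expert_value()` evaluates `phi(z, alpha) = (1 + z^2/2)^(-alpha)`, the
#' heavy-tailed expert applied to each filter response.
#' `expert_influence()` is the influence function
#' `psi(z, alpha) = alpha * z / (1 + z^2/2)`, the derivative of
#' `-log phi`; it is odd and bounded by `alpha / sqrt(2)`.
#'
#' @param z Filter response(s); numeric.
#' @param alpha Positive shape parameter (plays the role of degrees of
#'   freedom).
#' @return Numeric of the same shape as `z`.
#' @export
expert_value <- function(z, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single positive number", call. = FALSE)
  (1 + z^2 / 2)^(-alpha)
}

#' @rdname expert_value
#' @export
expert_influence <- function(z, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single positive number", call. = FALSE)
  alpha * z / (1 + z^2 / 2)
}

as_image_matrix <- function(x) {
  if (inherits(x, "pet_image")) x$values else as.matrix(x)
}

# Valid-region linear filtering: z[p,q] = sum_{u,v} k[u,v] x[p+u-1, q+v-1].
# (Cross-correlation; the mirrored kernel turns it into convolution. The
# prior gradient uses the exact adjoint of this operator, so either naming
# convention yields a gradient consistent with foe_energy.)
filter_valid <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  n <- nrow(x) - kh + 1L; m <- ncol(x) - kw + 1L
  if (n < 1L || m < 1L)
    stop("image smaller than filter kernel", call. = FALSE)
  out <- matrix(0, n, m)
  for (u in seq_len(kh)) for (v in seq_len(kw)) {
    if (k[u, v] != 0)
      out <- out + k[u, v] * x[u:(u + n - 1L), v:(v + m - 1L)]
  }
  out
}

# Adjoint of filter_valid: scatters a valid-size response map r back to
# image size (zero beyond the valid support).
filter_valid_adjoint <- function(r, k, dim_out) {
  kh <- nrow(k); kw <- ncol(k)
  n <- nrow(r); m <- ncol(r)
  out <- matrix(0, dim_out[1], dim_out[2])
  for (u in seq_len(kh)) for (v in seq_len(kw)) {
    if (k[u, v] != 0)
      out[u:(u + n - 1L), v:(v + m - 1L)] <-
        out[u:(u + n - 1L), v:(v + m - 1L)] + k[u, v] * r
  }
  out
}

#' Field-of-Experts energy of an image
#'
#' Evaluates `E(x) = sum_k sum_p alpha_k * log(1 + z_kp^2/2)` where
#' `z_kp` is the response of expert filter `k` at valid position `p`
#' (positions where the kernel lies fully inside the image; no padding).
#' This is the negative log of the unnormalized prior. Each term is
#' `-log phi >= 0`, so the energy is non-negative.
#'
#' @param x A [activity_image()] or numeric matrix, at least as large as
#'   the kernels.
#' @param bank A [filter_bank()].
#' @return An object of class `foe_energy`: list with `value` (total) and
#'   `per_expert` (length-`K` partial energies summing to `value`).
#' @export
foe_energy <- function(x, bank) {
  stopifnot(inherits(bank, "foe_filter_bank"))
  xm <- as_image_matrix(x)
  per <- vapply(seq_along(bank$filters), function(k) {
    z <- filter_valid(xm, bank$filters[[k]])
    bank$alphas[k] * sum(log1p(z^2 / 2))
  }, numeric(1))
  structure(list(value = sum(per), per_expert = per), class = "foe_energy")
}

#' @export
print.foe_energy <- function(x, ...) {
  cat(sprintf("foe_energy: %.6g over %d experts\n",
              x$value, length(x$per_expert)))
  invisible(x)
}

#' Gradient of the Field-of-Experts energy
#'
#' Computes `grad E(x) = sum_k Jmirror^(k) * psi_k(J^(k) * x)` with the
#' influence function `psi_k(z) = alpha_k z / (1 + z^2/2)`. Boundary
#' handling matches [foe_energy()] exactly (valid region only, response
#' maps scattered back by the adjoint filter operator), so the gradient
#' is the exact derivative of the stated energy — verified against finite
#' differences in the test suite.
#'
#' @inheritParams foe_energy
#' @return Numeric matrix of the image's shape.
#' @export
foe_gradient <- function(x, bank) {
  stopifnot(inherits(bank, "foe_filter_bank"))
  xm <- as_image_matrix(x)
  g <- matrix(0, nrow(xm), ncol(xm))
  for (k in seq_along(bank$filters)) {
    z <- filter_valid(xm, bank$filters[[k]])
    psi <- expert_influence(z, bank$alphas[k])
    g <- g + filter_valid_adjoint(psi, bank$filters[[k]], dim(xm))
  }
  g
}

project_zero_mean <- function(J) sweep(J, 2, colMeans(J))

# Energy gradient w.r.t. a batch of vectorized patches (d x B), used by
# the CD sampler. Jmat: d x K filter matrix.
patch_energy_grad <- function(X, Jmat, alphas) {
  Z <- crossprod(Jmat, X)                      # K x B responses
  Psi <- alphas * Z / (1 + Z^2 / 2)
  Jmat %*% Psi
}

#' Train expert filters by contrastive divergence
#'
#' Learns a [filter_bank()] from image patches: zero-mean random filters
#' and unit shape parameters are refined by CD-1 with Langevin sampling.
#' Each update starts short stochastic-gradient chains at a minibatch of
#' (DC-removed) data patches, runs `langevin_steps` Langevin steps under
#' the current model, and moves the filter coefficients and `log alpha_k`
#' along the difference between the data and model expectations of the
#' energy gradient. Filters are projected back to zero mean after every
#' update. Fully seeded and deterministic.
#'
#' @param training_images List of [activity_image()]s or matrices, each
#'   larger than `patch_size`.
#' @param K Number of expert filters to learn.
#' @param patch_size Side of the square filters (default 5).
#' @param n_patches Number of patches sampled from the corpus.
#' @param n_iter Number of CD parameter updates.
#' @param batch_size Minibatch size per update.
#' @param eta Learning rate for filter coefficients.
#' @param eta_alpha Learning rate for `log alpha`.
#' @param langevin_steps,langevin_step Number and size of Langevin steps.
#' @param seed Integer seed.
#' @return A [filter_bank()] with zero-mean filters and training
#'   provenance.
#' @export
train_filters_cd <- function(training_images, K, patch_size = 5,
                             n_patches = 5000, n_iter = 300,
                             batch_size = 500, eta = 0.05,
                             eta_alpha = 0.02, langevin_steps = 1,
                             langevin_step = 0.05, seed = 0) {
  stopifnot(K >= 1, patch_size >= 1, length(training_images) >= 1)
  mats <- lapply(training_images, as_image_matrix)
  if (any(vapply(mats, function(m)
    nrow(m) < patch_size || ncol(m) < patch_size, logical(1))))
    stop("training images must be at least patch_size in each dimension",
         call. = FALSE)
  d <- patch_size^2

  with_seed(seed, {
    # -- sample patches, remove per-patch DC
    P <- matrix(0, d, n_patches)
    img_idx <- sample.int(length(mats), n_patches, replace = TRUE)
    for (t in seq_len(n_patches)) {
      m <- mats[[img_idx[t]]]
      r0 <- sample.int(nrow(m) - patch_size + 1L, 1L)
      c0 <- sample.int(ncol(m) - patch_size + 1L, 1L)
      P[, t] <- as.vector(m[r0:(r0 + patch_size - 1L),
                            c0:(c0 + patch_size - 1L)])
    }
    P <- sweep(P, 2, colMeans(P))
    sc <- stats::sd(P)
    if (!is.finite(sc) || sc < 1e-12)
      stop("degenerate (constant) training set: patches carry no structure",
           call. = FALSE)
    P <- P / sc                                 # unit overall scale

    Jmat <- matrix(stats::rnorm(d * K, sd = 0.1), d, K)
    Jmat <- project_zero_mean(Jmat)
    log_alpha <- rep(0, K)
    bsz <- min(batch_size, n_patches)

    for (it in seq_len(n_iter)) {
      alphas <- exp(log_alpha)
      X0 <- P[, sample.int(n_patches, bsz), drop = FALSE]
      # short Langevin chains started at the data
      X <- X0
      for (s in seq_len(langevin_steps)) {
        g <- patch_energy_grad(X, Jmat, alphas)
        X <- X - langevin_step * g +
          sqrt(2 * langevin_step) * matrix(stats::rnorm(d * bsz), d, bsz)
        X <- sweep(X, 2, colMeans(X))           # stay in the zero-DC subspace
      }
      Z0 <- crossprod(Jmat, X0); Z1 <- crossprod(Jmat, X)
      Psi0 <- alphas * Z0 / (1 + Z0^2 / 2)
      Psi1 <- alphas * Z1 / (1 + Z1^2 / 2)
      # dE/dJ_k = psi_k(z) x  -> d x K matrices of batch means
      dJ <- (X0 %*% t(Psi0) - X %*% t(Psi1)) / bsz
      Jmat <- project_zero_mean(Jmat - eta * dJ)
      # dE/dlog(alpha_k) = alpha_k log(1 + z^2/2)
      e0 <- rowMeans(alphas * log1p(Z0^2 / 2))
      e1 <- rowMeans(alphas * log1p(Z1^2 / 2))
      log_alpha <- pmin(pmax(log_alpha - eta_alpha * (e0 - e1),
                             log(0.05)), log(100))
      if (any(!is.finite(Jmat)) || any(!is.finite(log_alpha)))
        stop("contrastive-divergence training diverged", call. = FALSE)
    }

    filters <- lapply(seq_len(K), function(k)
      matrix(Jmat[, k], patch_size, patch_size))
    filter_bank(filters, exp(log_alpha),
                provenance = list(
                  method = "contrastive divergence (CD-1, Langevin)",
                  n_patches = n_patches, n_iter = n_iter,
                  batch_size = bsz, eta = eta, eta_alpha = eta_alpha,
                  langevin_steps = langevin_steps,
                  langevin_step = langevin_step, seed = seed,
                  patch_scale = sc,
                  n_training_images = length(mats)))
  })
}

# Recover a list of K kernel matrices from a parsed JSON payload, which
# jsonlite may hand back as a K x h x w array, a list of matrices, or a
# list of row lists, depending on regularity.
kernels_from_json <- function(kern, K, ks) {
  out <- if (is.array(kern) && length(dim(kern)) == 3L) {
    lapply(seq_len(dim(kern)[1]), function(k)
      matrix(kern[k, , ], dim(kern)[2], dim(kern)[3]))
  } else if (is.list(kern)) {
    lapply(kern, function(m)
      if (is.list(m)) do.call(rbind, lapply(m, as.numeric)) else as.matrix(m))
  } else stop("malformed filter bank file: unreadable kernels",
              call. = FALSE)
  if (length(out) != K)
    stop("malformed filter bank file: expected ", K, " kernels, found ",
         length(out), call. = FALSE)
  for (k in seq_along(out)) {
    if (!identical(dim(out[[k]]), ks))
      stop("malformed filter bank file: kernel ", k, " has wrong shape",
           call. = FALSE)
  }
  out
}

#' Read or write a filter bank file
#'
#' The bank is stored as a small versioned JSON container carrying the
#' kernels, the shape parameters and the training provenance; the
#' round-trip is lossless.
#'
#' @param bank A [filter_bank()].
#' @param path File path.
#' @return `read_filter_bank()` returns a [filter_bank()];
#'   `write_filter_bank()` returns `path` invisibly.
#' @export
write_filter_bank <- function(bank, path) {
  stopifnot(inherits(bank, "foe_filter_bank"))
  d <- dim(bank$filters[[1]])
  obj <- list(format = "petfoe_filter_bank", version = 1L,
              K = length(bank$filters), kernel_size = d,
              kernels = bank$filters,
              alphas = bank$alphas, provenance = bank$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed filter bank file: ", conditionMessage(e),
                         call. = FALSE))
  if (!identical(obj$format, "petfoe_filter_bank"))
    stop("malformed filter bank file: missing format marker", call. = FALSE)
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported filter bank schema version: ", obj$version,
         call. = FALSE)
  ks <- as.integer(obj$kernel_size)
  filters <- kernels_from_json(obj$kernels, as.integer(obj$K), ks)
  prov <- if (is.null(obj$provenance)) list() else as.list(obj$provenance)
  filter_bank(filters, as.numeric(obj$alphas), provenance = prov)
}

#' The package's default filter bank
#'
#' Loads the bank shipped with the package: 24 zero-mean 5x5 filters with
#' learned shape parameters, trained by [train_filters_cd()] on synthetic
#' phantom images (see [synthetic_training_images()]). It is a synthetic
#' stand-in for banks trained on clinical image corpora; users with their
#' own training data can substitute any bank written by
#' [write_filter_bank()].
#'
#' @return A [filter_bank()].
#' @export
default_filter_bank <- function() {
  path <- system.file("extdata", "default_foe_bank.json", package = "petfoe",
                      mustWork = TRUE)
  read_filter_bank(path)
}

#' Rescale a filter bank's total expert weight
#'
#' Multiplies all shape parameters by a common factor so that
#' `sum(alphas) == alpha_total`. Used to normalize the overall strength
#' of a trained prior: contrastive divergence fixes the *relative*
#' expert weights, but the absolute scale of the energy (and hence how
#' strongly a fixed regularization weight `beta` smooths) depends on the
#' training corpus. Pinning the total weight makes banks of different
#' provenance comparable under one `beta`.
#'
#' @param bank A [filter_bank()].
#' @param alpha_total Desired `sum(alphas)` (> 0).
#' @return A [filter_bank()] with rescaled `alphas`.
#' @export
rescale_filter_bank <- function(bank, alpha_total) {
  stopifnot(inherits(bank, "foe_filter_bank"), alpha_total > 0)
  prov <- bank$provenance
  prov$alpha_total <- alpha_total
  filter_bank(bank$filters, bank$alphas * alpha_total / sum(bank$alphas),
              provenance = prov)
}

#' Synthetic training images for filter learning
#'
#' Generates activity images resembling reconstructed emission scans:
#' random multi-ellipse "anatomy" with nested uptake levels, overlaid
#' with multiplicative noise at relative level `noise_sd` (reconstructed
#' PET images carry residual noise texture, and a prior trained on
#' noise-free piecewise-constant images would be far too confident).
#' Purely synthetic; no clinical data.
#'
#' @param n Number of images.
#' @param size Image side in pixels.
#' @param seed Integer seed.
#' @param noise_sd Relative multiplicative noise level (0 disables).
#' @return List of numeric matrices.
#' @export
synthetic_training_images <- function(n = 20, size = 64, seed = 0,
                                      noise_sd = 0.25) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      x <- seq(-1, 1, length.out = size)
      X <- matrix(x, size, size, byrow = TRUE)
      Y <- matrix(rev(x), size, size)
      img <- matrix(0, size, size)
      n_ell <- sample(3:6, 1)
      for (e in seq_len(n_ell)) {
        cx <- stats::runif(1, -0.5, 0.5); cy <- stats::runif(1, -0.5, 0.5)
        a <- stats::runif(1, 0.1, 0.7); b <- stats::runif(1, 0.1, 0.7)
        th <- stats::runif(1, 0, pi)
        act <- stats::runif(1, 0.5, 8)
        u <- cos(th) * (X - cx) + sin(th) * (Y - cy)
        v <- -sin(th) * (X - cx) + cos(th) * (Y - cy)
        img[(u / a)^2 + (v / b)^2 <= 1] <- act
      }
      if (noise_sd > 0)
        img <- pmax(img * (1 + noise_sd *
                             matrix(stats::rnorm(size^2), size, size)), 0)
      img
    })
  })
}
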