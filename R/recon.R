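# Iterative reconstruction: ML-EM, the cross-entropy gradient scheme MXE,
# the FoE-regularized MXE, and the one-step-late relative-difference
# (CP) baseline. All schemes share the multiplicative/variable-step
# structure x_j <- x_j - (x_j / s_j) * grad_j with s_j the sensitivity
# (column sums of A); pixels with s_j = 0 are frozen at 0 and bins whose
# rays miss the field of view are skipped rather than divided by.

sino_values <- function(y) if (inherits(y, "pet_sinogram")) y$values else as.matrix(y)

#' Cross-entropy (Kullback-Leibler) data fidelity
#'
#' `D(y, ybar) = sum_i [ y_i ln y_i - y_i ln ybar_i - y_i + ybar_i ]`
#' with the convention `0 ln 0 = 0`. Non-negative, zero iff `y = ybar`
#' on the support of `y`; `+Inf` when `ybar_i = 0` at a bin with
#' `y_i > 0`. Minimizing `D(y, A x)` over `x` is equivalent to
#' maximizing the Poisson log-likelihood.
#'
#' @param y Measured counts ([sinogram()] or numeric).
#' @param ybar Expected counts, same shape.
#' @return Scalar divergence.
#' @export
cross_entropy <- function(y, ybar) {
  yv <- as.vector(sino_values(y)); bv <- as.vector(sino_values(ybar))
  if (length(yv) != length(bv)) stop("shape mismatch", call. = FALSE)
  if (any(yv < 0) || any(bv < 0))
    stop("cross_entropy requires non-negative inputs", call. = FALSE)
  pos <- yv > 0
  if (any(bv[pos] == 0)) return(Inf)
  sum(yv[pos] * (log(yv[pos]) - log(bv[pos]))) - sum(yv) + sum(bv)
}

#' Poisson log-likelihood (constant term dropped)
#'
#' `sum_i [ -ybar_i + y_i ln ybar_i ]`; the data-only `ln(y_i!)` term is
#' omitted, as it shifts all traces by a constant.
#'
#' @inheritParams cross_entropy
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(y, ybar) {
  yv <- as.vector(sino_values(y)); bv <- as.vector(sino_values(ybar))
  if (length(yv) != length(bv)) stop("shape mismatch", call. = FALSE)
  pos <- yv > 0
  if (any(bv[pos] == 0)) return(-Inf)
  sum(yv[pos] * log(bv[pos])) - sum(bv)
}

# epsilon guard for ratio denominators: 1e-12 x mean positive count.
default_epsilon <- function(y) {
  yv <- as.vector(sino_values(y))
  m <- if (any(yv > 0)) mean(yv[yv > 0]) else 1
  1e-12 * m
}

# Backprojection of the data/estimate ratio y/q, the workhorse of every
# scheme. Bins with y = 0 contribute nothing; bins with q below epsilon
# (and y > 0) are guarded.
ratio_backproject <- function(x_vec, y_vec, A, epsilon) {
  q <- as.numeric(A$entries %*% x_vec)
  r <- numeric(length(q))
  pos <- y_vec > 0
  r[pos] <- y_vec[pos] / pmax(q[pos], epsilon)
  as.numeric(Matrix::crossprod(A$entries, r))
}

#' One ML-EM update
#'
#' The classical multiplicative update
#' `x_j <- (x_j / s_j) * sum_i a_ij y_i / (A x)_i`. Non-negativity is
#' automatic; zero-sensitivity pixels stay 0.
#'
#' @param x Current estimate ([activity_image()]).
#' @param y Measured [sinogram()].
#' @param A [build_system_matrix()] result.
#' @param epsilon Positive guard for vanishing denominators; default
#'   `1e-12` times the mean positive count.
#' @return Updated [activity_image()].
#' @export
em_step <- function(x, y, A, epsilon = default_epsilon(y)) {
  stopifnot(inherits(A, "pet_system_matrix"))
  xv <- as.vector(as_image_matrix(x)); yv <- as.vector(sino_values(y))
  s <- A$sensitivity
  if (all(xv == 0) && sum(yv) > 0)
    warning("EM started from the all-zero image: fixed point at 0, no progress possible")
  bp <- ratio_backproject(xv, yv, A, epsilon)
  xn <- numeric(length(xv))
  live <- s > 0
  xn[live] <- xv[live] / s[live] * bp[live]
  activity_image(matrix(xn, nrow = A$geometry$n_pixels_y), A$geometry)
}

#' One MXE cross-entropy gradient-descent update
#'
#' A gradient step on the cross-entropy `J0(x) = D(y, A x)` with the
#' variable per-pixel step size `x_j / s_j`:
#' `x_j <- x_j - (x_j / s_j) * dJ0/dx_j`, where
#' `dJ0/dx_j = sum_i [ a_ij - a_ij y_i / (A x)_i ]`. Algebraically this
#' is the ML-EM update in disguise; the identity is asserted by the test
#' suite rather than assumed.
#'
#' @inheritParams em_step
#' @return Updated [activity_image()].
#' @export
mxe1_step <- function(x, y, A, epsilon = default_epsilon(y)) {
  stopifnot(inherits(A, "pet_system_matrix"))
  xv <- as.vector(as_image_matrix(x)); yv <- as.vector(sino_values(y))
  s <- A$sensitivity
  grad <- s - ratio_backproject(xv, yv, A, epsilon)
  xn <- numeric(length(xv))
  live <- s > 0
  xn[live] <- xv[live] - xv[live] / s[live] * grad[live]
  # x - (x/s)(s - bp) = (x/s) bp >= 0 exactly; the subtraction form can
  # leave -eps-level residue when bp ~ 0
  xn[xn < 0] <- 0
  activity_image(matrix(xn, nrow = A$geometry$n_pixels_y), A$geometry)
}

#' One FoE-regularized MXE update with non-negativity safeguard
#'
#' A gradient step on the penalized objective
#' `J(x) = D(y, A x) + beta * E(x)` (cross-entropy fidelity plus the
#' Field-of-Experts energy) with step size `x_j / s_j`, followed by the
#' non-negativity safeguard of [nonneg_safeguard()]: negative proposals
#' are clamped to zero and the step is backtracked until the objective
#' does not increase.
#'
#' @inheritParams em_step
#' @param bank A [filter_bank()].
#' @param beta Regularization weight (default 0.5).
#' @param safeguard If `FALSE`, only clamp negatives (no backtracking).
#' @param max_backtracks Step-halving budget of the safeguard.
#' @return Updated [activity_image()] with attributes `clips` (pixels
#'   clamped to 0) and `backtracks`.
#' @export
mxe_foe_step <- function(x, y, A, bank, beta = 0.5,
                         epsilon = default_epsilon(y),
                         safeguard = TRUE, max_backtracks = 10) {
  stopifnot(inherits(A, "pet_system_matrix"),
            inherits(bank, "foe_filter_bank"))
  geom <- A$geometry
  xm <- as_image_matrix(x)
  xv <- as.vector(xm); yv <- as.vector(sino_values(y))
  s <- A$sensitivity
  grad <- s - ratio_backproject(xv, yv, A, epsilon)
  if (beta > 0) grad <- grad + beta * as.vector(foe_gradient(xm, bank))
  prop <- numeric(length(xv))
  live <- s > 0
  prop[live] <- xv[live] - xv[live] / s[live] * grad[live]
  prop_m <- matrix(prop, nrow = geom$n_pixels_y)

  objective <- function(img_m) {
    q <- as.numeric(A$entries %*% as.vector(img_m))
    ce <- cross_entropy(yv, q)
    if (beta > 0) ce + beta * foe_energy(img_m, bank)$value else ce
  }
  if (!safeguard) {
    clipped <- pmax(prop_m, 0)
    out <- activity_image(clipped, geom)
    attr(out, "clips") <- sum(prop_m < 0)
    attr(out, "backtracks") <- 0L
    return(out)
  }
  nonneg_safeguard(activity_image(xm, geom), prop_m, objective,
                   max_backtracks = max_backtracks)
}

#' Non-negativity safeguard with backtracking
#'
#' Clamps negative entries of a proposed iterate to zero; if the clamped
#' iterate fails to decrease the objective, the step toward it is halved
#' (and re-clamped) up to `max_backtracks` times. Returns the first
#' non-increasing iterate, or the previous iterate if every backtrack
#' fails — so the objective never increases across an accepted step.
#'
#' @param x_prev Previous (feasible, non-negative) [activity_image()].
#' @param x_proposed Proposed update; numeric matrix, may be negative.
#' @param objective Function of an image matrix returning the scalar
#'   objective to be decreased.
#' @param max_backtracks Maximum step halvings.
#' @return [activity_image()] with attributes `clips` and `backtracks`.
#' @export
nonneg_safeguard <- function(x_prev, x_proposed, objective,
                             max_backtracks = 10) {
  stopifnot(inherits(x_prev, "pet_image"))
  prev_m <- x_prev$values
  prop_m <- as.matrix(x_proposed)
  f_prev <- objective(prev_m)
  step <- prop_m - prev_m
  scale <- 1
  for (t in 0:max_backtracks) {
    cand <- prev_m + scale * step
    clips <- sum(cand < 0)
    cand[cand < 0] <- 0
    if (objective(cand) <= f_prev) {
      out <- activity_image(cand, x_prev$geometry)
      attr(out, "clips") <- clips
      attr(out, "backtracks") <- t
      return(out)
    }
    scale <- scale / 2
  }
  out <- x_prev
  attr(out, "clips") <- 0L
  attr(out, "backtracks") <- max_backtracks + 1L
  out
}

# Relative-difference penalty over 8-neighborhoods (ordered pairs):
#   R(x) = sum_j sum_{k in N8(j)} (x_j - x_k)^2 /
#          (x_j + x_k + gamma |x_j - x_k| + eps)
# cp_penalty returns R; cp_penalty_gradient its exact gradient (both
# directed terms of a pair contribute identically to dR/dx_j).
neighbor_offsets8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                           dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Relative-difference penalty and its gradient
#'
#' The edge-tolerant concave penalty on neighboring pixel differences
#' used by the CP baseline: squared differences normalized by local
#' activity plus `gamma` times the absolute difference, summed over
#' 8-neighbor pairs (both directions).
#'
#' @param x Image ([activity_image()] or matrix).
#' @param gamma Edge parameter (>= 0).
#' @param eps Small positive stabilizer in the denominator.
#' @return `cp_penalty()`: scalar; `cp_penalty_gradient()`: matrix of the
#'   image's shape.
#' @export
cp_penalty <- function(x, gamma = 0.1, eps = 1e-9) {
  xm <- as_image_matrix(x)
  nr <- nrow(xm); nc <- ncol(xm)
  total <- 0
  for (o in seq_len(nrow(neighbor_offsets8))) {
    dr <- neighbor_offsets8[o, 1]; dc <- neighbor_offsets8[o, 2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- xm[r1, c1, drop = FALSE]
    b <- xm[r1 + dr, c1 + dc, drop = FALSE]
    d <- a - b
    total <- total + sum(d^2 / (a + b + gamma * abs(d) + eps))
  }
  total
}

#' @rdname cp_penalty
#' @export
cp_penalty_gradient <- function(x, gamma = 0.1, eps = 1e-9) {
  xm <- as_image_matrix(x)
  nr <- nrow(xm); nc <- ncol(xm)
  g <- matrix(0, nr, nc)
  for (o in seq_len(nrow(neighbor_offsets8))) {
    dr <- neighbor_offsets8[o, 1]; dc <- neighbor_offsets8[o, 2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- xm[r1, c1, drop = FALSE]
    b <- xm[r1 + dr, c1 + dc, drop = FALSE]
    d <- a - b
    D <- a + b + gamma * abs(d) + eps
    g[r1, c1] <- g[r1, c1] + 2 * (2 * d / D - d^2 * (1 + gamma * sign(d)) / D^2)
  }
  g
}

#' One CP (relative-difference prior) one-step-late update
#'
#' Penalized EM with the relative-difference penalty evaluated at the
#' previous iterate (one-step-late device):
#' `x_j <- x_j * sum_i a_ij y_i/(Ax)_i / (s_j + beta_n dR/dx_j)`, where
#' the effective penalty weight decays geometrically,
#' `beta_n = cp_beta * cp_lambda^(n-1)`.
#'
#' @inheritParams em_step
#' @param cp_beta Penalty weight (default 0.01).
#' @param cp_gamma Edge parameter of the penalty (default 0.1).
#' @param cp_lambda Per-iteration geometric relaxation factor (default
#'   0.97).
#' @param iteration 1-based iteration number (sets `beta_n`).
#' @return Updated [activity_image()].
#' @export
cp_step <- function(x, y, A, cp_beta = 0.01, cp_gamma = 0.1,
                    cp_lambda = 0.97, iteration = 1,
                    epsilon = default_epsilon(y)) {
  stopifnot(inherits(A, "pet_system_matrix"))
  xm <- as_image_matrix(x)
  xv <- as.vector(xm); yv <- as.vector(sino_values(y))
  s <- A$sensitivity
  bp <- ratio_backproject(xv, yv, A, epsilon)
  beta_n <- cp_beta * cp_lambda^(iteration - 1)
  denom <- s + beta_n * as.vector(cp_penalty_gradient(xm, cp_gamma))
  xn <- numeric(length(xv))
  live <- s > 0
  denom <- pmax(denom, 0.1 * s)   # keep the OSL denominator positive
  xn[live] <- xv[live] * bp[live] / denom[live]
  activity_image(matrix(pmax(xn, 0), nrow = A$geometry$n_pixels_y),
                 A$geometry)
}

#' Reconstruction configuration
#'
#' @param algorithm One of `"EM"`, `"MXE1"`, `"MXE_FOE"`, `"CP"`.
#' @param n_iterations Iteration count. Defaults: 12 for EM/MXE1 (the
#'   count used for the unregularized baseline), 27 for MXE_FOE and CP.
#' @param beta FoE regularization weight (MXE_FOE; default 0.5).
#' @param cp_beta,cp_gamma,cp_lambda CP parameters (defaults 0.01, 0.1,
#'   0.97).
#' @param filter_bank [filter_bank()] for MXE_FOE; `NULL` loads the
#'   package default.
#' @param epsilon Division guard; `NULL` derives it from the data.
#' @param init_value Uniform initialization level; `NULL` scales the
#'   flat start so the projected counts match the measured total.
#' @param safeguard Use the backtracking non-negativity safeguard
#'   (MXE_FOE only); pure clamping when `FALSE`.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(algorithm = c("EM", "MXE1", "MXE_FOE", "CP"),
                         n_iterations = NULL, beta = 0.5,
                         cp_beta = 0.01, cp_gamma = 0.1, cp_lambda = 0.97,
                         filter_bank = NULL, epsilon = NULL,
                         init_value = NULL, safeguard = TRUE) {
  algorithm <- match.arg(algorithm)
  if (is.null(n_iterations))
    n_iterations <- switch(algorithm, EM = 12L, MXE1 = 12L,
                           MXE_FOE = 27L, CP = 27L)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (!is.null(epsilon) && epsilon <= 0)
    stop("epsilon must be > 0", call. = FALSE)
  if (!is.null(init_value) && init_value <= 0)
    stop("init_value must be > 0", call. = FALSE)
  structure(list(algorithm = algorithm, n_iterations = n_iterations,
                 beta = beta, cp_beta = cp_beta, cp_gamma = cp_gamma,
                 cp_lambda = cp_lambda, filter_bank = filter_bank,
                 epsilon = epsilon, init_value = init_value,
                 safeguard = isTRUE(safeguard)),
            class = "recon_config")
}

#' Reconstruct a sinogram
#'
#' Runs the configured algorithm from a uniform positive start (scaled so
#' the projected initial counts match the measured total) and records a
#' per-iteration objective trace: Poisson log-likelihood for EM,
#' cross-entropy `J0` for MXE1, the penalized cross-entropy `J_FoE` for
#' MXE_FOE, and the penalized log-likelihood for CP. Deterministic for
#' fixed inputs.
#'
#' @param y Measured [sinogram()].
#' @param A [build_system_matrix()] result.
#' @param config A [recon_config()].
#' @return An object of class `pet_recon_result`: `image`,
#'   `objective_trace` (length `n_iterations`), `negativity_clips`, and
#'   the `config` (with defaults resolved).
#' @examples
#' geom <- pet_geometry(24, 24, 2, n_radial = 32, n_angles = 30)
#' A <- build_system_matrix(geom)
#' ph <- make_rod_phantom(rod_phantom_spec(body_diameter = 40,
#'                                         rod_diameters = c(5, 7),
#'                                         rods_per_row = 2), geom)
#' y <- simulate_sinogram(A, ph, 2e4, seed = 7)
#' fit <- reconstruct(y, A, recon_config("EM"))
#' fit$objective_trace
#' @export
reconstruct <- function(y, A, config = recon_config()) {
  stopifnot(inherits(config, "recon_config"),
            inherits(A, "pet_system_matrix"))
  yv <- as.vector(sino_values(y))
  s <- A$sensitivity
  epsilon <- if (is.null(config$epsilon)) default_epsilon(yv) else config$epsilon
  bank <- config$filter_bank
  if (config$algorithm == "MXE_FOE" && is.null(bank))
    bank <- default_filter_bank()
  init <- config$init_value
  if (is.null(init)) {
    denom <- sum(s[s > 0])
    init <- if (denom > 0 && sum(yv) > 0) sum(yv) / denom else 1
  }
  geom <- A$geometry
  xv <- ifelse(s > 0, init, 0)
  x <- activity_image(matrix(xv, nrow = geom$n_pixels_y), geom)

  n <- config$n_iterations
  trace <- numeric(n); clips <- integer(n)
  for (it in seq_len(n)) {
    if (config$algorithm == "EM") {
      x <- em_step(x, yv, A, epsilon)
    } else if (config$algorithm == "MXE1") {
      x <- mxe1_step(x, yv, A, epsilon)
    } else if (config$algorithm == "MXE_FOE") {
      x <- mxe_foe_step(x, yv, A, bank, beta = config$beta,
                        epsilon = epsilon, safeguard = config$safeguard)
      clips[it] <- attr(x, "clips")
    } else if (config$algorithm == "CP") {
      x <- cp_step(x, yv, A, config$cp_beta, config$cp_gamma,
                   config$cp_lambda, iteration = it, epsilon = epsilon)
    } else stop("unknown algorithm: ", config$algorithm, call. = FALSE)

    q <- as.numeric(A$entries %*% as.vector(x$values))
    trace[it] <- switch(
      config$algorithm,
      EM = poisson_loglik(yv, q),
      MXE1 = cross_entropy(yv, q),
      MXE_FOE = cross_entropy(yv, q) +
        config$beta * foe_energy(x$values, bank)$value,
      CP = poisson_loglik(yv, q) -
        config$cp_beta * config$cp_lambda^(it - 1) *
          cp_penalty(x$values, config$cp_gamma))
  }
  cfg <- config; cfg$epsilon <- epsilon; cfg$init_value <- init
  cfg$filter_bank <- bank
  structure(list(image = x, objective_trace = trace,
                 negativity_clips = clips, config = cfg),
            class = "pet_recon_result")
}

#' @export
print.pet_recon_result <- function(x, ...) {
  cat(sprintf("pet_recon_result: %s, %d iterations, final objective %.6g\n",
              x$config$algorithm, x$config$n_iterations,
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}
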