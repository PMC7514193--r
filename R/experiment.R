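# End-to-end study drivers: the rod-phantom contrast/noise study and the
# 25+25 lesion-detectability study, plus a manifest-producing experiment
# runner tying phantom -> system matrix -> simulation -> reconstruction
# -> evaluation together.

#' Default desk-scale acquisition geometry
#'
#' 96 x 96 image of 0.8 mm pixels with 128 radial bins x 120 angles —
#' the package's standard small-scale study geometry. `scale` shrinks
#' everything proportionally (e.g. `scale = 0.5` gives 48 x 48 with
#' 64 x 60 bins) for quicker replicated studies.
#'
#' @param scale Positive scale factor.
#' @return A [pet_geometry()].
#' @export
default_experiment_geometry <- function(scale = 1) {
  n <- max(8L, as.integer(round(96 * scale)))
  pet_geometry(n, n, pixel_size = 0.8 * 96 / n,
               n_radial = max(8L, as.integer(round(128 * scale))),
               n_angles = max(8L, as.integer(round(120 * scale))),
               radial_spacing = 0.8 * 96 / n)
}

#' Target/background ROIs for a rod phantom
#'
#' Target: a square inscribed in the rod nearest the row center of the
#' largest-diameter row. Background: an equal-size square in rod-free
#' body at 30% of the body diameter left of center.
#'
#' @param spec A [rod_phantom_spec()].
#' @param geometry A [pet_geometry()].
#' @return A [roi_spec()].
#' @export
rod_study_rois <- function(spec, geometry) {
  lay <- rod_layout(spec)
  if (!length(lay$d)) stop("rod phantom has no rods", call. = FALSE)
  k <- which(lay$d == max(lay$d))
  k <- k[which.min(abs(lay$cx[k]))]
  h <- max(1L, as.integer(floor(lay$d[k] / (2 * sqrt(2)) /
                                  geometry$pixel_size)))
  tc <- mm_to_pixel(geometry, c(lay$cx[k], lay$cy[k]))
  bc <- mm_to_pixel(geometry, c(-0.3 * spec$body_diameter, 0))
  sq <- function(cen) list(rows = (cen[1] - h):(cen[1] + h),
                           cols = (cen[2] - h):(cen[2] + h))
  roi_spec(target = sq(tc), background = sq(bc))
}

#' Rod-phantom contrast/noise study
#'
#' Simulates one low-count acquisition of the rod phantom and
#' reconstructs it with each configured algorithm, reporting the rod
#' contrast resolution, the background-ROI standard deviation (noise),
#' and the background-ROI mean for every method.
#'
#' @param A A [build_system_matrix()] result.
#' @param spec A [rod_phantom_spec()].
#' @param target_counts Expected total counts of the simulated scan.
#' @param algorithms Named list of [recon_config()]s.
#' @param seed Integer seed for the Poisson realization.
#' @return List with the simulated `sinogram`, the `roi` used, the true
#'   `phantom`, and per-algorithm entries (`recon`, `cr`,
#'   `background_sd`, `background_mean`).
#' @export
run_rod_study <- function(A, spec = rod_phantom_spec(),
                          target_counts = 5e5,
                          algorithms = list(
                            EM = recon_config("EM", n_iterations = 27),
                            MXE_FOE = recon_config("MXE_FOE")),
                          seed = 1) {
  phantom <- make_rod_phantom(spec, A$geometry)
  y <- simulate_sinogram(A, phantom, target_counts, seed)
  roi <- rod_study_rois(spec, A$geometry)
  per_algo <- lapply(algorithms, function(cfg) {
    fit <- reconstruct(y, A, cfg)
    bg <- fit$image$values[roi$background$rows, roi$background$cols]
    list(recon = fit,
         cr = contrast_resolution(fit$image, roi),
         background_sd = stats::sd(as.vector(bg)),
         background_mean = mean(bg))
  })
  c(list(sinogram = y, roi = roi, phantom = phantom, seed = seed,
         target_counts = target_counts), per_algo)
}

#' Lesion-detectability study with a channelized Hotelling observer
#'
#' Replicates the 25-vs-25 study design: `n_per_class` signal-present
#' realizations (a circular lesion of known location, by default 10 at
#' 5x local background and 15 at 3x) and `n_per_class` signal-absent
#' realizations are simulated at a low count level, reconstructed with
#' each configured algorithm, and fed to [cho_auc()].
#'
#' @param A A [build_system_matrix()] result.
#' @param spec A [lesion_phantom_spec()]; its `lesion_activity_ratio` is
#'   overridden per realization by `contrasts`.
#' @param contrasts Lesion-to-background ratios for the present class,
#'   length `n_per_class` (default `c(rep(5, 10), rep(3, 15))`).
#' @param n_per_class Realizations per class (default 25).
#' @param target_counts Expected total counts per realization.
#' @param algorithms Named list of [recon_config()]s.
#' @param seed Master seed; per-realization seeds are drawn from it.
#' @param patch_halfwidth,n_channels,ridge,method Observer settings, see
#'   [cho_auc()].
#' @return List with per-algorithm `auc` (named numeric), the observer
#'   `method`, the lesion `center` (pixels), and the per-realization
#'   seeds.
#' @export
run_cho_study <- function(A, spec = lesion_phantom_spec(),
                          contrasts = c(rep(5, 10), rep(3, 15)),
                          n_per_class = 25, target_counts = 2e5,
                          algorithms = list(
                            EM = recon_config("EM"),
                            MXE_FOE = recon_config("MXE_FOE")),
                          seed = 1, patch_halfwidth = 6, n_channels = 4,
                          ridge = 1e-6, method = "resubstitution") {
  stopifnot(length(contrasts) == n_per_class)
  geom <- A$geometry
  absent_truth <- make_lesion_phantom(spec, geom, with_lesion = FALSE)
  present_truths <- lapply(unique(contrasts), function(ct) {
    s <- spec; s$lesion_activity_ratio <- ct
    make_lesion_phantom(s, geom, with_lesion = TRUE)
  })
  names(present_truths) <- as.character(unique(contrasts))
  center <- mm_to_pixel(geom, spec$lesion_center)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          2L * n_per_class))

  recon_one <- function(truth, sd) {
    y <- simulate_sinogram(A, truth, target_counts, sd)
    lapply(algorithms, function(cfg) reconstruct(y, A, cfg)$image)
  }
  present <- lapply(seq_len(n_per_class), function(i)
    recon_one(present_truths[[as.character(contrasts[i])]], sub_seeds[i]))
  absent <- lapply(seq_len(n_per_class), function(i)
    recon_one(absent_truth, sub_seeds[n_per_class + i]))

  auc <- vapply(names(algorithms), function(nm) {
    cho_auc(lapply(present, `[[`, nm), lapply(absent, `[[`, nm),
            center = center, patch_halfwidth = patch_halfwidth,
            n_channels = n_channels, ridge = ridge, method = method)$auc
  }, numeric(1))
  list(auc = auc, method = method, center = center, seeds = sub_seeds,
       target_counts = target_counts, contrasts = contrasts)
}

#' Experiment configuration
#'
#' Bundles every choice of an end-to-end run — geometry, phantom,
#' count level, seed, the algorithms to compare, and the evaluation ROI —
#' so that [run_experiment()] is a pure function of it.
#'
#' @param geometry A [pet_geometry()].
#' @param phantom_spec A [rod_phantom_spec()] or [lesion_phantom_spec()].
#' @param target_counts Expected total counts.
#' @param seed Integer seed.
#' @param recon_configs Named list of [recon_config()]s.
#' @param roi Optional [roi_spec()]; defaults to [rod_study_rois()] for
#'   rod phantoms.
#' @param output_dir Optional directory; when given, all artifacts are
#'   written there as containers and the manifest as JSON.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(geometry = default_experiment_geometry(),
                              phantom_spec = rod_phantom_spec(),
                              target_counts = 5e5, seed = 1,
                              recon_configs = list(
                                EM = recon_config("EM", n_iterations = 27),
                                MXE_FOE = recon_config("MXE_FOE")),
                              roi = NULL, output_dir = NULL) {
  if (is.null(names(recon_configs)) || any(names(recon_configs) == ""))
    stop("recon_configs must be a named list", call. = FALSE)
  structure(list(geometry = geometry, phantom_spec = phantom_spec,
                 target_counts = target_counts, seed = as.integer(seed),
                 recon_configs = recon_configs, roi = roi,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Run an end-to-end experiment
#'
#' Executes phantom generation, system-matrix construction, Poisson
#' simulation, reconstruction with every configured algorithm, and ROI
#' evaluation, and returns a manifest echoing every parameter together
#' with the metric values. Rerunning with the same configuration
#' reproduces the manifest exactly. When `output_dir` is set, phantom,
#' sinogram and reconstructions are written as containers next to a
#' `manifest.json`.
#'
#' @param config An [experiment_config()].
#' @return The manifest (named list), invisibly written to disk when
#'   requested.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  geom <- config$geometry
  A <- build_system_matrix(geom)
  is_rod <- inherits(config$phantom_spec, "rod_phantom_spec")
  phantom <- if (is_rod) make_rod_phantom(config$phantom_spec, geom)
  else make_lesion_phantom(config$phantom_spec, geom, with_lesion = TRUE)
  y <- simulate_sinogram(A, phantom, config$target_counts, config$seed)
  roi <- config$roi
  if (is.null(roi) && is_rod) roi <- rod_study_rois(config$phantom_spec, geom)

  fits <- lapply(config$recon_configs, function(cfg) reconstruct(y, A, cfg))
  metrics <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    m <- list(algorithm = fit$config$algorithm,
              n_iterations = fit$config$n_iterations,
              beta = fit$config$beta,
              cp_beta = fit$config$cp_beta,
              cp_gamma = fit$config$cp_gamma,
              cp_lambda = fit$config$cp_lambda,
              final_objective = fit$objective_trace[fit$config$n_iterations],
              total_clips = sum(fit$negativity_clips))
    if (!is.null(roi)) {
      bg <- fit$image$values[roi$background$rows, roi$background$cols]
      m$cr <- contrast_resolution(fit$image, roi)
      m$background_sd <- stats::sd(as.vector(bg))
    }
    m
  })
  names(metrics) <- names(fits)

  manifest <- list(
    geometry = geometry_to_list(geom),
    phantom = unclass(config$phantom_spec),
    phantom_kind = if (is_rod) "rod" else "lesion",
    target_counts = config$target_counts,
    seed = config$seed,
    roi = if (is.null(roi)) NULL else unclass(roi),
    metrics = metrics)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_container(phantom, file.path(config$output_dir, "phantom.json"))
    write_container(y, file.path(config$output_dir, "sinogram.json"))
    files <- c(phantom = "phantom.json", sinogram = "sinogram.json")
    for (nm in names(fits)) {
      fn <- paste0("recon_", nm, ".json")
      write_container(fits[[nm]], file.path(config$output_dir, fn))
      files[[paste0("recon_", nm)]] <- fn
    }
    manifest$files <- as.list(files)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  manifest$fits <- fits
  invisible(manifest)
}
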