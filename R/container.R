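# One versioned JSON container for all array artifacts (images,
# sinograms, geometries, system matrices in triplet form, filter banks,
# reconstruction results). Plain text, lossless round-trip, validated on
# read.

CONTAINER_FORMAT <- "petfoe_container"
CONTAINER_VERSION <- 1L

geometry_to_list <- function(g) unclass(g)
geometry_from_list <- function(l) {
  pet_geometry(l$n_pixels_x, l$n_pixels_y, l$pixel_size, l$n_radial,
               l$n_angles, l$radial_spacing, as.numeric(l$angles))
}

#' Write a package object to a JSON container
#'
#' Serializes geometries, activity images, sinograms, system matrices
#' (as sparse triplets), filter banks, and reconstruction results to one
#' self-describing versioned JSON file. [read_container()] restores the
#' object and re-validates its invariants, so a corrupted file (for
#' example a sinogram with negative counts) is rejected at read time
#' with an error naming the offending dataset.
#'
#' @param object One of the package's data objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(object, path) {
  payload <- if (inherits(object, "pet_geometry")) {
    list(type = "geometry", geometry = geometry_to_list(object))
  } else if (inherits(object, "pet_image")) {
    list(type = "image", geometry = geometry_to_list(object$geometry),
         values = object$values)
  } else if (inherits(object, "pet_sinogram")) {
    list(type = "sinogram", geometry = geometry_to_list(object$geometry),
         values = object$values,
         seed = attr(object, "seed"),
         target_counts = attr(object, "target_counts"))
  } else if (inherits(object, "pet_system_matrix")) {
    trip <- methods::as(object$entries, "TsparseMatrix")
    list(type = "system_matrix",
         geometry = geometry_to_list(object$geometry),
         i = trip@i + 1L, j = trip@j + 1L, weights = trip@x,
         dims = dim(object$entries))
  } else if (inherits(object, "foe_filter_bank")) {
    list(type = "filter_bank", kernels = object$filters,
         K = length(object$filters),
         kernel_size = dim(object$filters[[1]]),
         alphas = object$alphas, provenance = object$provenance)
  } else if (inherits(object, "pet_recon_result")) {
    cfg <- object$config
    list(type = "recon_result",
         geometry = geometry_to_list(object$image$geometry),
         image = object$image$values,
         objective_trace = object$objective_trace,
         negativity_clips = object$negativity_clips,
         algorithm = cfg$algorithm, n_iterations = cfg$n_iterations,
         beta = cfg$beta, cp_beta = cfg$cp_beta, cp_gamma = cfg$cp_gamma,
         cp_lambda = cfg$cp_lambda, epsilon = cfg$epsilon,
         init_value = cfg$init_value, safeguard = cfg$safeguard)
  } else stop("unsupported object class: ", paste(class(object), collapse = "/"),
              call. = FALSE)
  obj <- c(list(format = CONTAINER_FORMAT, version = CONTAINER_VERSION),
           payload)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed container file: ", conditionMessage(e),
                         call. = FALSE))
  if (!identical(obj$format, CONTAINER_FORMAT))
    stop("not a petfoe container (missing format marker)", call. = FALSE)
  if (!identical(as.integer(obj$version), CONTAINER_VERSION))
    stop("unsupported container schema version: ", obj$version,
         " (this build reads version ", CONTAINER_VERSION, ")",
         call. = FALSE)
  need <- function(name) {
    if (is.null(obj[[name]]))
      stop("corrupt container: missing dataset `", name, "`", call. = FALSE)
    obj[[name]]
  }
  type <- need("type")
  wrap <- function(expr, name) tryCatch(expr, error = function(e)
    stop("invalid dataset `", name, "` in container: ",
         conditionMessage(e), call. = FALSE))
  if (type == "geometry") {
    wrap(geometry_from_list(need("geometry")), "geometry")
  } else if (type == "image") {
    g <- wrap(geometry_from_list(need("geometry")), "geometry")
    wrap(activity_image(as.matrix(need("values")), g), "values")
  } else if (type == "sinogram") {
    g <- wrap(geometry_from_list(need("geometry")), "geometry")
    out <- wrap(sinogram(as.matrix(need("values")), g), "values")
    if (!is.null(obj$seed)) attr(out, "seed") <- as.integer(obj$seed)
    if (!is.null(obj$target_counts))
      attr(out, "target_counts") <- obj$target_counts
    out
  } else if (type == "system_matrix") {
    g <- wrap(geometry_from_list(need("geometry")), "geometry")
    w <- need("weights")
    if (any(w < 0))
      stop("invalid dataset `weights` in container: negative entries",
           call. = FALSE)
    A <- Matrix::sparseMatrix(i = as.integer(need("i")),
                              j = as.integer(need("j")), x = as.numeric(w),
                              dims = as.integer(need("dims")))
    structure(list(geometry = g, entries = A,
                   sensitivity = as.numeric(Matrix::colSums(A))),
              class = "pet_system_matrix")
  } else if (type == "filter_bank") {
    ks <- as.integer(need("kernel_size"))
    filters <- kernels_from_json(need("kernels"), as.integer(need("K")), ks)
    prov <- if (is.null(obj$provenance)) list() else as.list(obj$provenance)
    wrap(filter_bank(filters, as.numeric(need("alphas")), prov), "alphas")
  } else if (type == "recon_result") {
    g <- wrap(geometry_from_list(need("geometry")), "geometry")
    img <- wrap(activity_image(as.matrix(need("image")), g), "image")
    cfg <- recon_config(need("algorithm"),
                        n_iterations = need("n_iterations"),
                        beta = obj$beta, cp_beta = obj$cp_beta,
                        cp_gamma = obj$cp_gamma, cp_lambda = obj$cp_lambda,
                        epsilon = obj$epsilon, init_value = obj$init_value,
                        safeguard = obj$safeguard)
    structure(list(image = img,
                   objective_trace = as.numeric(need("objective_trace")),
                   negativity_clips = as.integer(obj$negativity_clips),
                   config = cfg),
              class = "pet_recon_result")
  } else stop("unknown container type: ", type, call. = FALSE)
}
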