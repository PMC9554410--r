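#' Latent codes and latent pools
#'
#' A latent code is one face's coordinates in the generator's extended latent
#' space: an L x D real matrix, one D-vector per style layer (defaults
#' L = 18 layers of D = 512 dimensions, the extended-latent geometry of
#' common style-based face generators).  A latent pool is an ordered, shape-homogeneous
#' collection of such codes with provenance metadata; it stands in for the
#' pool of inverted neutral photographs from which stimuli are built.
#'
#' @param values numeric matrix (L rows = style layers, D columns).
#' @param id character identifier, unique within a pool.
#' @return `latent_code()` returns an object of class `"latent_code"`: a list
#'   with elements `id` and `values`.
#' @examples
#' lc <- latent_code(matrix(rnorm(6), 2, 3), id = "face1")
#' dim(lc$values)
#' @export
latent_code <- function(values, id = "code") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("latent matrix must have L >= 1 rows and D >= 1 columns", call. = FALSE)
  if (!all(is.finite(values)))
    stop("latent matrix entries must all be finite", call. = FALSE)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("id must be a non-empty string", call. = FALSE)
  structure(list(id = id, values = unname(values)), class = "latent_code")
}

#' @export
print.latent_code <- function(x, ...) {
  cat(sprintf("<latent_code '%s': %d x %d>\n", x$id,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

is_latent_code <- function(x) inherits(x, "latent_code")

latent_shape <- function(code) dim(code$values)

check_homogeneous <- function(codes) {
  if (length(codes) == 0L) stop("empty input", call. = FALSE)
  if (!all(vapply(codes, is_latent_code, logical(1))))
    stop("all elements must be latent_code objects", call. = FALSE)
  shp <- latent_shape(codes[[1L]])
  for (c in codes[-1L]) {
    if (!identical(latent_shape(c), shp))
      stop("heterogeneous shapes", call. = FALSE)
  }
  shp
}

#' Elementwise mean of latent codes
#'
#' Averages the latent matrices of a set of faces elementwise.  This is the
#' core averaging primitive behind stimulus creation (means of random 10-face
#' subsets) and the per-participant category means.
#'
#' @param codes non-empty list of [latent_code()] objects with identical shape.
#' @param id id for the resulting code.
#' @return A [latent_code()] holding the elementwise arithmetic mean.
#' @examples
#' a <- latent_code(matrix(c(0, 4, 2, 6), 2, 2), "a")
#' b <- latent_code(matrix(c(2, 0, 2, 2), 2, 2), "b")
#' mean_latents(list(a, b))$values
#' @export
mean_latents <- function(codes, id = NULL) {
  shp <- check_homogeneous(codes)
  acc <- matrix(0, shp[1L], shp[2L])
  for (c in codes) acc <- acc + c$values
  id <- id %||% paste0("mean(", paste(vapply(codes, `[[`, "", "id"),
                                      collapse = ","), ")")
  latent_code(acc / length(codes), id = id)
}

#' Add i.i.d. Gaussian noise to a latent code
#'
#' Perturbs every matrix entry independently with Normal(mu, sigma^2) noise;
#' stimulus generation defaults to mu = 0, sigma = 0.4 in raw latent units,
#' one sigma shared by all layers.
#'
#' @param code a [latent_code()].
#' @param sigma non-negative noise standard deviation.
#' @param seed integer seed for the draw.
#' @param mu noise mean (default 0).
#' @param id id for the resulting code.
#' @return A new [latent_code()]; the input is unmodified.
#' @export
add_noise <- function(code, sigma, seed, mu = 0, id = NULL) {
  stopifnot(is_latent_code(code))
  stopifnot_scalar_number(sigma, "sigma")
  stopifnot_scalar_number(mu, "mu")
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  shp <- latent_shape(code)
  noise <- with_seed(seed, matrix(stats::rnorm(prod(shp), mean = mu, sd = sigma),
                                  shp[1L], shp[2L]))
  latent_code(code$values + noise, id = id %||% paste0(code$id, "+noise"))
}

#' Flatten a latent code to a vector (and back)
#'
#' Row-major (layer-major) flattening: layer 1's D values first, then layer 2,
#' and so on.  The convention is fixed so that correlations, serialization and
#' observer projections all agree.
#'
#' @param code a [latent_code()].
#' @return `flatten_latent()`: numeric vector of length L*D.
#' @export
flatten_latent <- function(code) {
  stopifnot(is_latent_code(code))
  as.vector(t(code$values))
}

#' @rdname flatten_latent
#' @param x numeric vector of length `L * D`.
#' @param L,D target matrix dimensions.
#' @param id id for the reconstructed code.
#' @return `unflatten_latent()`: the [latent_code()] whose row-major
#'   flattening is `x`.
#' @export
unflatten_latent <- function(x, L, D, id = "code") {
  if (length(x) != L * D)
    stop(sprintf("vector length %d does not match L*D = %d", length(x), L * D),
         call. = FALSE)
  latent_code(matrix(x, nrow = L, ncol = D, byrow = TRUE), id = id)
}

flatten_values <- function(values) as.vector(t(values))

#' Construct a latent pool
#'
#' @param codes list of [latent_code()] objects; ids must be unique and
#'   shapes identical.
#' @param metadata named list of free-form provenance (source, seed,
#'   generation parameters, ...).
#' @return An object of class `"latent_pool"`: list with `codes` (named by
#'   id), `L`, `D` and `metadata`.
#' @export
latent_pool <- function(codes, metadata = list()) {
  shp <- check_homogeneous(codes)
  ids <- vapply(codes, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("latent ids must be unique within a pool", call. = FALSE)
  names(codes) <- ids
  structure(list(codes = codes, L = shp[1L], D = shp[2L], metadata = metadata),
            class = "latent_pool")
}

#' @export
print.latent_pool <- function(x, ...) {
  cat(sprintf("<latent_pool: %d codes, each %d x %d>\n",
              length(x$codes), x$L, x$D))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.latent_pool <- function(x) length(x$codes)

pool_ids <- function(pool) names(pool$codes)

#' Stack a pool's codes into a flattened matrix
#'
#' @param pool a [latent_pool()].
#' @return numeric matrix, one row per code (row-major flattened), rownames =
#'   ids.
#' @export
pool_matrix <- function(pool) {
  stopifnot(inherits(pool, "latent_pool"))
  m <- t(vapply(pool$codes, flatten_latent, numeric(pool$L * pool$D)))
  rownames(m) <- pool_ids(pool)
  m
}
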