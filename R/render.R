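#' Renderer backends
#'
#' Rendering a latent code to a face image requires the trained generator,
#' which this package deliberately does not ship.  Instead it exposes a
#' pluggable backend registry with the same contract a real generator would
#' satisfy — deterministic latent -> 8-bit raster image — plus a bundled
#' `"mock"` backend so the full pipeline (including image output) can be
#' exercised end to end.
#'
#' The mock backend applies a fixed, internally seeded linear projection of
#' the latent onto a 64 x 64 grayscale grid (`img = U %*% values %*% V` with
#' seeded Gaussian factors `U`, `V`, a linear map of the flattened latent),
#' then min–max scales to 0..255.  Same latent in, byte-identical image out.
#'
#' @param name backend name.
#' @param fun function `(latent_code) -> H x W x C` array of integers 0..255.
#' @name renderers
NULL

.renderers <- new.env(parent = emptyenv())

#' @rdname renderers
#' @export
register_renderer <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .renderers)
  invisible(name)
}

#' @rdname renderers
#' @return `list_renderers()`: character vector of registered backend names.
#' @export
list_renderers <- function() sort(ls(.renderers))

# Cache of mock projection factors per (L, D) shape.
.mock_proj <- new.env(parent = emptyenv())

mock_projection <- function(L, D, side = 64L) {
  key <- paste(L, D, side, sep = "x")
  if (!exists(key, envir = .mock_proj)) {
    # Fixed internal seed: the projection is part of the backend definition.
    UV <- with_seed(987654L, list(
      U = matrix(stats::rnorm(side * L), side, L),
      V = matrix(stats::rnorm(D * side), D, side)
    ))
    assign(key, UV, envir = .mock_proj)
  }
  get(key, envir = .mock_proj)
}

mock_render <- function(code, side = 64L) {
  pr <- mock_projection(nrow(code$values), ncol(code$values), side)
  img <- pr$U %*% code$values %*% pr$V
  rng <- range(img)
  img <- if (rng[2L] > rng[1L]) (img - rng[1L]) / (rng[2L] - rng[1L])
         else matrix(0, side, side)
  array(as.integer(round(img * 255)), dim = c(side, side, 1L))
}

#' Render a latent code with a registered backend
#'
#' @param code a [latent_code()].
#' @param backend backend name; see [list_renderers()].
#' @return Integer array `H x W x C` with values in 0..255.
#' @examples
#' img <- render_latent(latent_code(matrix(rnorm(8), 2, 4)), "mock")
#' dim(img)
#' @export
render_latent <- function(code, backend = "mock") {
  stopifnot(is_latent_code(code))
  if (!exists(backend, envir = .renderers))
    stop(sprintf("unknown renderer backend '%s'; registered backends: %s",
                 backend, paste(list_renderers(), collapse = ", ")),
         call. = FALSE)
  get(backend, envir = .renderers)(code)
}

#' Write a rendered image to a PNG file
#'
#' @param img integer array `H x W x C`, values 0..255 (as returned by
#'   [render_latent()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  stopifnot(is.array(img), length(dim(img)) == 3L)
  arr <- img / 255
  if (dim(arr)[3L] == 1L) arr <- arr[, , 1L]
  png::writePNG(arr, target = path)
  invisible(path)
}

register_default_renderers <- function() {
  register_renderer("mock", mock_render)
}
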