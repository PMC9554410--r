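#' Stimulus-generation configuration
#'
#' Holds the parameters of the two-step stimulus recipe: average the latents
#' of `k_average` faces sampled without replacement from the base pool, then
#' add i.i.d. Normal(mu, sigma^2) noise to every matrix entry.  Defaults:
#' 300 stimuli, 10-face subsets, mu = 0, sigma = 0.4.
#'
#' @param n_stimuli number of stimuli to generate (>= 1).
#' @param k_average subset size averaged per stimulus (>= 1).
#' @param mu noise mean.
#' @param sigma non-negative noise standard deviation.
#' @param seed master seed; the whole pool is a pure function of
#'   (base pool, config).
#' @return Object of class `"stimulus_config"`.
#' @export
stimulus_config <- function(n_stimuli = 300L, k_average = 10L,
                            mu = 0, sigma = 0.4, seed = 1L) {
  stopifnot_scalar_number(n_stimuli, "n_stimuli")
  stopifnot_scalar_number(k_average, "k_average")
  stopifnot_scalar_number(sigma, "sigma")
  stopifnot_scalar_number(mu, "mu")
  stopifnot_scalar_number(seed, "seed")
  if (n_stimuli < 1) stop("n_stimuli must be >= 1", call. = FALSE)
  if (k_average < 1) stop("k_average must be >= 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  structure(list(n_stimuli = as.integer(n_stimuli),
                 k_average = as.integer(k_average),
                 mu = mu, sigma = sigma, seed = as.integer(seed)),
            class = "stimulus_config")
}

#' Generate one stimulus from a latent pool
#'
#' Samples `k_average` distinct faces from the pool, averages their latents
#' elementwise, and adds Gaussian noise.  Provenance (source ids, noise seed)
#' is recorded on the returned entry.
#'
#' @param pool a [latent_pool()] with at least `k_average` codes.
#' @param config a [stimulus_config()].
#' @param seed seed for this stimulus (subset draw + noise).
#' @param stimulus_id id for the stimulus.
#' @return Object of class `"stimulus_entry"`: list with `stimulus_id`,
#'   `latent` ([latent_code()]), `source_ids`, `noise_seed`.
#' @export
generate_stimulus <- function(pool, config, seed, stimulus_id = "s0001") {
  stopifnot(inherits(pool, "latent_pool"), inherits(config, "stimulus_config"))
  if (length(pool) < config$k_average)
    stop(sprintf("pool has %d codes but k_average = %d",
                 length(pool), config$k_average), call. = FALSE)
  seeds <- derive_seeds(seed, 2L)
  ids <- with_seed(seeds[1L],
                   sample(pool_ids(pool), config$k_average, replace = FALSE))
  avg <- mean_latents(pool$codes[ids], id = stimulus_id)
  lat <- add_noise(avg, sigma = config$sigma, seed = seeds[2L],
                   mu = config$mu, id = stimulus_id)
  structure(list(stimulus_id = stimulus_id, latent = lat,
                 source_ids = ids, noise_seed = as.integer(seeds[2L])),
            class = "stimulus_entry")
}

#' @export
print.stimulus_entry <- function(x, ...) {
  cat(sprintf("<stimulus '%s': mean of %d faces + noise>\n",
              x$stimulus_id, length(x$source_ids)))
  invisible(x)
}

#' Generate the full stimulus pool
#'
#' Repeats [generate_stimulus()] `n_stimuli` times with per-stimulus seeds
#' derived from `config$seed`; the result is fully determined by the base
#' pool and the config.
#'
#' @inheritParams generate_stimulus
#' @return Object of class `"stimulus_pool"`: list with `entries` (ordered
#'   list of stimulus entries, ids `s0001`...), `L`, `D` and `config`.
#' @examples
#' pool <- simulate_latent_pool(n_faces = 12, L = 2, D = 4, seed = 7)
#' sp <- generate_stimulus_pool(pool, stimulus_config(n_stimuli = 5,
#'                                                    k_average = 3, seed = 1))
#' length(sp$entries)
#' @export
generate_stimulus_pool <- function(pool, config) {
  stopifnot(inherits(pool, "latent_pool"), inherits(config, "stimulus_config"))
  n <- config$n_stimuli
  seeds <- derive_seeds(config$seed, n)
  width <- max(4L, nchar(as.character(n)))
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf(paste0("s%0", width, "d"), i)
    entries[[i]] <- generate_stimulus(pool, config, seed = seeds[i],
                                      stimulus_id = sid)
  }
  structure(list(entries = entries, L = pool$L, D = pool$D, config = config),
            class = "stimulus_pool")
}

#' @export
print.stimulus_pool <- function(x, ...) {
  cat(sprintf(
    "<stimulus_pool: %d stimuli (%d x %d), k = %d, sigma = %g, seed = %d>\n",
    length(x$entries), x$L, x$D, x$config$k_average, x$config$sigma,
    x$config$seed))
  invisible(x)
}

stimulus_ids <- function(stimuli) {
  entries <- if (inherits(stimuli, "stimulus_pool")) stimuli$entries else stimuli
  vapply(entries, `[[`, "", "stimulus_id")
}

#' Stack stimulus latents into a flattened matrix
#'
#' @param stimuli a `stimulus_pool` or list of stimulus entries.
#' @return numeric matrix, one row per stimulus (row-major flattened latent),
#'   rownames = stimulus ids.
#' @export
stimulus_matrix <- function(stimuli) {
  entries <- if (inherits(stimuli, "stimulus_pool")) stimuli$entries else stimuli
  if (length(entries) == 0L) stop("no stimuli", call. = FALSE)
  n <- length(entries)
  m <- t(vapply(entries, function(e) flatten_latent(e$latent),
                numeric(prod(latent_shape(entries[[1L]]$latent)))))
  rownames(m) <- stimulus_ids(entries)
  m
}
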