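#' Generate a synthetic latent pool with planted attribute structure
#'
#' Stands in for a pool of real faces inverted into the generator's latent
#' space.  Each face is
#' \deqn{f = \bar{m} + \sum_j s_{fj}\, u_j + \epsilon_f,}
#' where the `u_j` are `n_factors` orthonormal flattened directions (the
#' planted attribute axes), `s_fj ~ N(0, factor_scale^2)` and
#' `epsilon ~ N(0, noise_scale^2)` i.i.d. per entry.  Because the factors are
#' returned in the pool metadata, recovery of a planted direction by the
#' reverse-correlation pipeline can be scored exactly.
#'
#' Defaults emulate a large inverted-photograph pool: 2,484 faces of shape
#' 18 x 512, with a
#' few dominant attribute axes (`n_factors = 4`, unit factor scale) over a
#' smaller isotropic residual (`noise_scale = 0.25`).
#'
#' @param n_faces number of faces.
#' @param L,D latent shape.
#' @param n_factors number of planted orthonormal attribute axes
#'   (`<= L * D`).
#' @param factor_scale standard deviation of the factor scores.
#' @param noise_scale standard deviation of the per-entry isotropic residual.
#' @param grand_mean optional length-`L*D` vector added to every face
#'   (default zero).
#' @param seed integer seed; the pool is a pure function of its arguments.
#' @return A [latent_pool()] whose `metadata` records all parameters plus
#'   `factors` (an `L*D x n_factors` orthonormal matrix) and `scores`.
#' @export
simulate_latent_pool <- function(n_faces, L = 18L, D = 512L, n_factors = 4L,
                                 factor_scale = 1, noise_scale = 0.25,
                                 grand_mean = NULL, seed = 1L) {
  stopifnot_scalar_number(n_faces, "n_faces")
  if (n_faces < 1) stop("n_faces must be >= 1", call. = FALSE)
  if (L < 1 || D < 1) stop("invalid latent dimensions", call. = FALSE)
  if (n_factors < 1 || n_factors > L * D)
    stop("n_factors must be in 1..L*D", call. = FALSE)
  if (factor_scale < 0 || noise_scale < 0)
    stop("scales must be non-negative", call. = FALSE)
  nd <- L * D
  gm <- grand_mean %||% numeric(nd)
  if (length(gm) != nd) stop("grand_mean must have length L*D", call. = FALSE)

  dat <- with_seed(seed, {
    raw <- matrix(stats::rnorm(nd * n_factors), nd, n_factors)
    factors <- qr.Q(qr(raw))[, seq_len(n_factors), drop = FALSE]
    scores <- matrix(stats::rnorm(n_faces * n_factors, sd = factor_scale),
                     n_faces, n_factors)
    noise <- matrix(stats::rnorm(n_faces * nd, sd = noise_scale), n_faces, nd)
    list(factors = factors, scores = scores,
         faces = sweep(scores %*% t(factors) + noise, 2L, gm, `+`))
  })

  width <- max(4L, nchar(as.character(n_faces)))
  codes <- lapply(seq_len(n_faces), function(i) {
    unflatten_latent(dat$faces[i, ], L, D,
                     id = sprintf(paste0("f%0", width, "d"), i))
  })
  latent_pool(codes, metadata = list(
    source = "synthetic", seed = as.integer(seed), n_faces = n_faces,
    L = L, D = D, n_factors = n_factors, factor_scale = factor_scale,
    noise_scale = noise_scale, factors = dat$factors, scores = dat$scores))
}

#' Simulated observers with shared and idiosyncratic preference axes
#'
#' Each observer judges stimuli by projecting them onto a personal unit
#' preference direction
#' \deqn{d_i = \mathrm{normalize}\big(w\,d_\mathrm{shared} + (1-w)\,e_i\big),}
#' with `e_i` i.i.d. uniform on the unit sphere.  The shared weight `w`
#' interpolates between fully idiosyncratic observers (`w = 0`) and perfectly
#' agreeing ones (`w = 1`); first-order attributes like masculinity behave
#' like high `w`, second-order attributes like trustworthiness like low `w`.
#'
#' @param shared_direction numeric vector (length `L*D`), the population's
#'   common preference axis; normalized internally.
#' @param n number of observers (>= 1).
#' @param w shared weight in `[0, 1]`.
#' @param tau non-negative decision threshold on the projection score.
#' @param lapse probability in `[0, 1)` of a uniformly random response.
#' @param seed integer seed.
#' @return list of `"observer"` objects: `observer_id`, `true_direction`
#'   (unit norm), `w`, `tau`, `lapse`, `seed`.
#' @export
make_observers <- function(shared_direction, n, w, tau = 0, lapse = 0,
                           seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (w < 0 || w > 1) stop("w must be in [0, 1]", call. = FALSE)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  if (lapse < 0 || lapse >= 1) stop("lapse must be in [0, 1)", call. = FALSE)
  nrmsh <- sqrt(sum(shared_direction^2))
  if (nrmsh == 0) stop("shared_direction must be non-zero", call. = FALSE)
  shared <- shared_direction / nrmsh
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    d <- with_seed(seeds[i], stats::rnorm(length(shared)))
    v <- w * shared + (1 - w) * d / sqrt(sum(d^2))
    v <- v / sqrt(sum(v^2))
    structure(list(observer_id = sprintf("obs%03d", i), true_direction = v,
                   w = w, tau = tau, lapse = lapse, seed = seeds[i]),
              class = "observer")
  })
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf("<observer '%s': w = %g, tau = %g, lapse = %g, dim %d>\n",
              x$observer_id, x$w, x$tau, x$lapse, length(x$true_direction)))
  invisible(x)
}

#' Simulate a three-way categorization session
#'
#' For each stimulus the observer computes the projection score
#' `<flatten(stimulus - anchor_reference), true_direction>` and responds
#' target if the score exceeds `tau`, opposite if it is below `-tau`, and
#' neither otherwise (exact ties fall to neither).  With probability `lapse`
#' the response is replaced by a uniformly random category.  Presentation
#' order is a seeded permutation of the stimulus pool, stored on the session.
#'
#' @param observer an observer from [make_observers()].
#' @param stimuli a `stimulus_pool` or list of stimulus entries.
#' @param anchor_reference [latent_code()] giving the observer's neutral
#'   point (typically the stimulus-pool grand mean); the analysis pipeline
#'   never sees it.
#' @param condition a [condition_spec()].
#' @param seed integer seed (presentation order, lapses).
#' @return An [rc_session()].
#' @export
simulate_session <- function(observer, stimuli, anchor_reference, condition,
                             seed = 1L) {
  stopifnot(inherits(observer, "observer"),
            inherits(condition, "condition_spec"),
            is_latent_code(anchor_reference))
  sm <- stimulus_matrix(stimuli)
  if (ncol(sm) != length(observer$true_direction))
    stop("observer direction length does not match stimulus latent size",
         call. = FALSE)
  centered <- sweep(sm, 2L, flatten_latent(anchor_reference), `-`)
  score <- as.vector(centered %*% observer$true_direction)
  resp <- ifelse(score > observer$tau, "target",
                 ifelse(score < -observer$tau, "opposite", "neither"))
  n <- nrow(sm)
  dat <- with_seed(seed, {
    ord <- sample.int(n)
    lapses <- stats::runif(n) < observer$lapse
    random_resp <- sample(.responses, n, replace = TRUE)
    list(ord = ord, lapses = lapses, random_resp = random_resp)
  })
  resp[dat$lapses] <- dat$random_resp[dat$lapses]
  sids <- rownames(sm)[dat$ord]
  trials <- data.frame(trial_index = seq_len(n), stimulus_id = sids,
                       response = resp[dat$ord], stringsAsFactors = FALSE)
  rc_session(observer$observer_id, condition, trials,
             presentation_order = sids)
}

#' Ground-truth variance components for simulated ratings
#'
#' @param mu grand mean.
#' @param var_participant,var_stimulus,var_interaction,var_residual
#'   non-negative variance components; at least one positive.
#' @return Object of class `"vpc_truth"`.
#' @export
vpc_truth <- function(mu = 0, var_participant = 0, var_stimulus = 0,
                      var_interaction = 0, var_residual = 0) {
  v <- c(participant = var_participant, stimulus = var_stimulus,
         interaction = var_interaction, residual = var_residual)
  if (any(v < 0)) stop("variance components must be non-negative", call. = FALSE)
  if (all(v == 0)) stop("at least one variance component must be positive",
                        call. = FALSE)
  structure(list(mu = mu, var = v), class = "vpc_truth")
}

#' Simulate a balanced cross-classified ratings table
#'
#' Draws from the additive random-effects model
#' \deqn{y_{ijk} = \mu + a_i + b_j + (ab)_{ij} + e_{ijk}}
#' with independent zero-mean Gaussian effects of the variances given in
#' `truth`.  The generative twin of [vpc()]: estimates from the simulated
#' table should recover `truth`'s variance shares as the design grows.
#'
#' @param truth a [vpc_truth()].
#' @param p,s number of participants / stimuli (>= 2 each).
#' @param r repetitions per cell (>= 1).
#' @param seed integer seed.
#' @return A balanced `ratings_table` with `p * s * r` rows.
#' @export
simulate_ratings <- function(truth, p, s, r, seed = 1L) {
  stopifnot(inherits(truth, "vpc_truth"))
  if (p < 2 || s < 2 || r < 1) stop("invalid design: need p,s >= 2, r >= 1",
                                    call. = FALSE)
  p <- as.integer(p); s <- as.integer(s); r <- as.integer(r)
  eff <- with_seed(seed, list(
    a = stats::rnorm(p, sd = sqrt(truth$var[["participant"]])),
    b = stats::rnorm(s, sd = sqrt(truth$var[["stimulus"]])),
    ab = matrix(stats::rnorm(p * s, sd = sqrt(truth$var[["interaction"]])), p, s),
    e = array(stats::rnorm(p * s * r, sd = sqrt(truth$var[["residual"]])),
              c(p, s, r))
  ))
  idx <- expand.grid(k = seq_len(r), j = seq_len(s), i = seq_len(p))
  y <- truth$mu + eff$a[idx$i] + eff$b[idx$j] +
    eff$ab[cbind(idx$i, idx$j)] + eff$e[cbind(idx$i, idx$j, idx$k)]
  as_ratings_table(data.frame(
    participant_id = sprintf("p%03d", idx$i),
    stimulus_id = sprintf("s%04d", idx$j),
    repetition = idx$k, rating = y, stringsAsFactors = FALSE))
}
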