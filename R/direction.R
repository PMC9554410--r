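#' Fit a per-participant directional-vector model
#'
#' The estimator at the heart of latent-space reverse correlation.  Let
#' `Abar` be the elementwise mean latent of the stimuli the participant
#' categorized as the target attribute, `Bbar` the mean latent of the
#' opposite-categorized stimuli, and `N` the mean latent of the
#' "neither"-categorized stimuli.  The model is
#'
#' \deqn{A = \bar{A} - \bar{B}, \qquad M_C = N + C \cdot A,}
#'
#' where `A` is the participant's directional vector (moving along it
#' intensifies the perceived attribute), `N` is the participant's neutral
#' anchor, and `M_C` is the mental-representation latent at intensity `C`.
#' Means are taken over the latents of the noised stimuli actually shown.
#' If the participant never chose "neither", the anchor falls back to the
#' mean of `fallback_n` stimuli sampled uniformly without replacement from
#' the full pool (default 20); the fallback changes only
#' the anchor, never the direction.
#'
#' @param session an [rc_session()] with at least one target and one opposite
#'   selection.
#' @param stimuli the `stimulus_pool` (or list of stimulus entries) the
#'   session refers to.
#' @param fallback_n number of stimuli averaged for the fallback anchor.
#' @param seed seed for the fallback draw; required only when the session has
#'   no "neither" selections.
#' @return Object of class `"direction_model"` with elements
#'   `participant_id`, `condition`, `target_mean`, `opposite_mean`, `anchor`
#'   (all [latent_code()]), `direction` (`target_mean - opposite_mean`,
#'   exactly), `anchor_is_fallback`, `n_target`, `n_opposite`, `n_neither`,
#'   `L`, `D`.
#' @seealso [extrapolate()], [representation_series()], [pairwise_agreement()]
#' @examples
#' pool <- simulate_latent_pool(n_faces = 30, L = 2, D = 5, seed = 3)
#' sp <- generate_stimulus_pool(pool, stimulus_config(20, 5, seed = 4))
#' obs <- make_observers(stats::rnorm(10), n = 1, w = 1, seed = 5)[[1]]
#' sess <- simulate_session(obs, sp, anchor_reference = pool$codes[[1]],
#'                          condition = condition_spec("masculine", "feminine"),
#'                          seed = 6)
#' fit <- direction_model(sess, sp, seed = 7)
#' fit
#' @export
direction_model <- function(session, stimuli, fallback_n = 20L, seed = NULL) {
  stopifnot(inherits(session, "rc_session"))
  entries <- if (inherits(stimuli, "stimulus_pool")) stimuli$entries else stimuli
  ids <- stimulus_ids(entries)
  viol <- validate_session(session, entries)
  if (length(viol))
    stop(paste(c("session does not match stimulus pool:", viol),
               collapse = "\n  "), call. = FALSE)
  lat_by_id <- lapply(entries, `[[`, "latent")
  names(lat_by_id) <- ids

  pick <- function(resp) {
    sel <- session$trials$stimulus_id[session$trials$response == resp]
    lat_by_id[sel]
  }
  tgt <- pick("target"); opp <- pick("opposite"); nei <- pick("neither")
  if (length(tgt) == 0L || length(opp) == 0L)
    stop("degenerate session: direction undefined (need at least one target and one opposite selection)",
         call. = FALSE)

  pid <- session$participant_id
  target_mean <- mean_latents(tgt, id = paste0(pid, ":target_mean"))
  opposite_mean <- mean_latents(opp, id = paste0(pid, ":opposite_mean"))
  direction <- latent_code(target_mean$values - opposite_mean$values,
                           id = paste0(pid, ":direction"))

  anchor_is_fallback <- length(nei) == 0L
  if (anchor_is_fallback) {
    if (is.null(seed))
      stop("no 'neither' selections: supply a seed for the fallback anchor draw",
           call. = FALSE)
    fallback_n <- min(as.integer(fallback_n), length(entries))
    sel <- with_seed(seed, sample(ids, fallback_n, replace = FALSE))
    anchor <- mean_latents(lat_by_id[sel], id = paste0(pid, ":anchor_fallback"))
  } else {
    anchor <- mean_latents(nei, id = paste0(pid, ":anchor"))
  }

  structure(list(participant_id = pid, condition = session$condition,
                 target_mean = target_mean, opposite_mean = opposite_mean,
                 anchor = anchor, direction = direction,
                 anchor_is_fallback = anchor_is_fallback,
                 n_target = length(tgt), n_opposite = length(opp),
                 n_neither = length(nei),
                 L = nrow(direction$values), D = ncol(direction$values)),
            class = "direction_model")
}

#' @export
print.direction_model <- function(x, ...) {
  cat(sprintf("Directional-vector model for participant '%s' (%s)\n",
              x$participant_id, condition_name(x$condition)))
  cat(sprintf("  latent shape: %d x %d\n", x$L, x$D))
  cat(sprintf("  selections: %d target, %d opposite, %d neither%s\n",
              x$n_target, x$n_opposite, x$n_neither,
              if (x$anchor_is_fallback) " (anchor from fallback sample)" else ""))
  cat(sprintf("  |direction| = %.4g\n", sqrt(sum(x$direction$values^2))))
  invisible(x)
}

#' @export
summary.direction_model <- function(object, ...) {
  out <- list(participant_id = object$participant_id,
              condition = condition_name(object$condition),
              shape = c(L = object$L, D = object$D),
              counts = c(target = object$n_target,
                         opposite = object$n_opposite,
                         neither = object$n_neither),
              anchor_is_fallback = object$anchor_is_fallback,
              direction_norm = sqrt(sum(object$direction$values^2)),
              anchor_norm = sqrt(sum(object$anchor$values^2)))
  class(out) <- "summary.direction_model"
  out
}

#' @export
print.summary.direction_model <- function(x, ...) {
  cat(sprintf("Directional-vector model: participant '%s', condition %s\n",
              x$participant_id, x$condition))
  cat(sprintf("  %d x %d latent; counts: %d/%d/%d (target/opposite/neither)%s\n",
              x$shape["L"], x$shape["D"], x$counts["target"],
              x$counts["opposite"], x$counts["neither"],
              if (x$anchor_is_fallback) "; fallback anchor" else ""))
  cat(sprintf("  |direction| = %.4g, |anchor| = %.4g\n",
              x$direction_norm, x$anchor_norm))
  invisible(x)
}

#' @export
coef.direction_model <- function(object, ...) object$direction$values

#' Extrapolate a directional model at intensity C
#'
#' Computes `M_C = anchor + C * direction`, exactly.  `C = 0` returns the
#' anchor; `C = 1` is the participant's baseline representation.  Constants
#' beyond +/-8 trigger a warning, not an error: rendered images typically
#' degrade outside that range, but the arithmetic is well defined.
#'
#' @param model a [direction_model()].
#' @param C finite scalar intensity constant.
#' @return A [latent_code()].
#' @export
extrapolate <- function(model, C) {
  stopifnot(inherits(model, "direction_model"))
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C))
    stop("C must be a single finite number", call. = FALSE)
  if (abs(C) > 8)
    warning(sprintf("|C| = %g exceeds 8; rendered images typically degrade beyond +/-8",
                    abs(C)))
  latent_code(model$anchor$values + C * model$direction$values,
              id = sprintf("%s:M[%g]", model$participant_id, C))
}

#' @export
predict.direction_model <- function(object, constants = seq(-8, 8, by = 2), ...) {
  if (length(constants) == 1L) extrapolate(object, constants)
  else representation_series(object, constants)
}

#' Series of extrapolated representations
#'
#' Evaluates the model along a ladder of intensity constants (default
#' -8, -6, ..., +8, the usable rendering range).  Differences between rendered
#' representations become visually apparent from about +/-4 outward, so the
#' series carries that visibility heuristic in its metadata.
#'
#' @param model a [direction_model()].
#' @param constants non-empty numeric vector of intensity constants.
#' @return Object of class `"representation_series"`: list with `constants`,
#'   `latents` (one [latent_code()] per constant), `model` summary fields and
#'   `visibility_threshold` (4).
#' @export
representation_series <- function(model, constants = seq(-8, 8, by = 2)) {
  stopifnot(inherits(model, "direction_model"))
  if (length(constants) == 0L)
    stop("constants must be non-empty", call. = FALSE)
  if (!all(is.finite(constants)))
    stop("constants must all be finite", call. = FALSE)
  latents <- lapply(constants, function(C) extrapolate(model, C))
  structure(list(participant_id = model$participant_id,
                 constants = as.numeric(constants), latents = latents,
                 visibility_threshold = 4),
            class = "representation_series")
}

#' @export
print.representation_series <- function(x, ...) {
  cat(sprintf("<representation series for '%s': C = %s>\n", x$participant_id,
              paste(x$constants, collapse = ", ")))
  cat(sprintf("  (differences typically visible from |C| >= %g)\n",
              x$visibility_threshold))
  invisible(x)
}

#' Render a model's representation series as an image grid
#'
#' @param x a [direction_model()].
#' @param constants intensity constants, one panel each.
#' @param backend renderer backend name (default the bundled mock).
#' @param ... ignored.
#' @return Invisibly, the list of rendered arrays.
#' @export
plot.direction_model <- function(x, constants = c(-8, -4, 0, 4, 8),
                                 backend = "mock", ...) {
  series <- representation_series(x, constants)
  imgs <- lapply(series$latents, render_latent, backend = backend)
  old <- graphics::par(mfrow = c(1, length(imgs)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_along(imgs)) {
    img <- imgs[[i]][, , 1L]
    graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(256),
                    axes = FALSE, main = sprintf("C = %g", constants[i]))
  }
  invisible(imgs)
}

#' Pearson correlation between two latent codes
#'
#' Correlates the two latents after row-major flattening (the default,
#' whole-matrix reading of agreement between representations); optionally
#' correlates layer by layer and averages the per-layer coefficients.
#'
#' @param a,b [latent_code()] objects of identical shape.
#' @param method `"flat"` (Pearson on the L*D-vectors) or `"per_layer"`
#'   (mean of the L per-row Pearson coefficients).
#' @return Correlation in `[-1, 1]`.
#' @export
latent_pearson <- function(a, b, method = c("flat", "per_layer")) {
  method <- match.arg(method)
  stopifnot(is_latent_code(a), is_latent_code(b))
  if (!identical(latent_shape(a), latent_shape(b)))
    stop("heterogeneous shapes", call. = FALSE)
  if (method == "flat") {
    va <- flatten_latent(a); vb <- flatten_latent(b)
    if (stats::sd(va) == 0 || stats::sd(vb) == 0)
      stop("undefined correlation: zero-variance input", call. = FALSE)
    stats::cor(va, vb)
  } else {
    rs <- vapply(seq_len(nrow(a$values)), function(i) {
      ra <- a$values[i, ]; rb <- b$values[i, ]
      if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
        stop("undefined correlation: zero-variance layer", call. = FALSE)
      stats::cor(ra, rb)
    }, numeric(1))
    mean(rs)
  }
}

#' Inter-participant agreement of extrapolated representations
#'
#' Extrapolates every model at the same intensity `C` and computes the
#' Pearson correlation between each unordered pair of (flattened)
#' representations.  High mean pairwise correlation indicates shared mental
#' representations of the attribute; low values indicate idiosyncratic ones.
#' By default agreement is computed on the full representation `M_C`
#' (anchor included); `include_anchor = FALSE` correlates `C * direction`
#' alone.
#'
#' @param models list of at least two [direction_model()] objects with equal
#'   latent shape.
#' @param C intensity constant at which to compare (conventionally the
#'   extremes +/-8).
#' @param method correlation variant, see [latent_pearson()].
#' @param include_anchor include the anchor in the compared representations.
#' @return Object of class `"agreement"`: list with `mean_r`, `pairs`
#'   (symmetric correlation matrix, participants on both axes), `n_pairs`,
#'   `C`, `method`.
#' @export
pairwise_agreement <- function(models, C, method = c("flat", "per_layer"),
                               include_anchor = TRUE) {
  method <- match.arg(method)
  if (!is.list(models) || length(models) < 2L)
    stop("need at least two models", call. = FALSE)
  stopifnot(all(vapply(models, inherits, logical(1), "direction_model")))
  shp <- c(models[[1L]]$L, models[[1L]]$D)
  for (m in models)
    if (!identical(c(m$L, m$D), shp))
      stop("heterogeneous shapes", call. = FALSE)
  reps <- lapply(models, function(m) {
    if (include_anchor) extrapolate(m, C)
    else latent_code(C * m$direction$values, id = paste0(m$participant_id, ":CA"))
  })
  k <- length(reps)
  pairs <- diag(1, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r <- latent_pearson(reps[[i]], reps[[j]], method = method)
    pairs[i, j] <- pairs[j, i] <- r
  }
  pid <- vapply(models, `[[`, "", "participant_id")
  dimnames(pairs) <- list(pid, pid)
  ut <- pairs[upper.tri(pairs)]
  structure(list(mean_r = mean(ut), pairs = pairs,
                 n_pairs = length(ut), C = C, method = method,
                 include_anchor = include_anchor),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("Pairwise agreement at C = %g (%s%s): mean r = %.3f over %d pairs\n",
              x$C, x$method,
              if (x$include_anchor) "" else ", direction only",
              x$mean_r, x$n_pairs))
  invisible(x)
}
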