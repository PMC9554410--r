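#' Read and write latent pools
#'
#' Pools are stored as a CSV with header `id,v0,...,v{L*D-1}` (row-major
#' flattened latents, written at full decimal precision so the round trip is
#' bit-exact) plus a YAML sidecar `<path>.meta.yaml` holding `L`, `D` and any
#' provenance metadata.  Large in-memory metadata (planted factor matrices
#' from the synthetic generator) is not serialized.
#'
#' @param pool a [latent_pool()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `read_latent_pool()`: a [latent_pool()].
#' @export
write_latent_pool <- function(pool, path) {
  stopifnot(inherits(pool, "latent_pool"))
  m <- pool_matrix(pool)
  header <- c("id", paste0("v", seq_len(ncol(m)) - 1L))
  lines <- c(paste(header, collapse = ","),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], format_full(m[i, ])), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  meta <- pool$metadata
  meta <- meta[setdiff(names(meta), c("factors", "scores", "L", "D"))]
  yaml::write_yaml(c(list(L = pool$L, D = pool$D), meta),
                   sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' @rdname write_latent_pool
#' @export
read_latent_pool <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  if (is.null(meta$L) || is.null(meta$D))
    stop("pool sidecar must record L and D", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "id")
    stop("latent pool CSV must start with an 'id' column", call. = FALSE)
  L <- as.integer(meta$L); D <- as.integer(meta$D)
  if (ncol(df) - 1L != L * D)
    stop(sprintf("latent pool CSV has %d value columns, expected L*D = %d",
                 ncol(df) - 1L, L * D), call. = FALSE)
  codes <- lapply(seq_len(nrow(df)), function(i) {
    unflatten_latent(as.numeric(df[i, -1L]), L, D, id = df$id[i])
  })
  meta$L <- NULL; meta$D <- NULL
  latent_pool(codes, metadata = meta)
}

#' Read and write stimulus pools
#'
#' A stimulus pool is written as two files under a common prefix: the latent
#' CSV (+ sidecar, see [write_latent_pool()]) at `<prefix>_latents.csv`, and
#' a provenance CSV `<prefix>_provenance.csv` with columns
#' `stimulus_id,source_ids,noise_seed` (source ids semicolon-joined).  The
#' sidecar records the generation config.
#'
#' @param stimuli a `stimulus_pool`.
#' @param prefix file-path prefix.
#' @return `read_stimulus_pool()`: a `stimulus_pool` (its `config` restored
#'   from the sidecar).
#' @export
write_stimulus_pool <- function(stimuli, prefix) {
  stopifnot(inherits(stimuli, "stimulus_pool"))
  codes <- lapply(stimuli$entries, `[[`, "latent")
  cfg <- stimuli$config
  pool <- latent_pool(codes, metadata = list(
    kind = "stimulus_pool", n_stimuli = cfg$n_stimuli,
    k_average = cfg$k_average, mu = cfg$mu, sigma = cfg$sigma,
    seed = cfg$seed))
  write_latent_pool(pool, paste0(prefix, "_latents.csv"))
  prov <- data.frame(
    stimulus_id = stimulus_ids(stimuli),
    source_ids = vapply(stimuli$entries,
                        function(e) paste(e$source_ids, collapse = ";"), ""),
    noise_seed = vapply(stimuli$entries, `[[`, integer(1), "noise_seed"))
  utils::write.csv(prov, paste0(prefix, "_provenance.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_stimulus_pool
#' @export
read_stimulus_pool <- function(prefix) {
  pool <- read_latent_pool(paste0(prefix, "_latents.csv"))
  prov <- utils::read.csv(paste0(prefix, "_provenance.csv"),
                          stringsAsFactors = FALSE)
  meta <- pool$metadata
  cfg <- stimulus_config(n_stimuli = meta$n_stimuli, k_average = meta$k_average,
                         mu = meta$mu, sigma = meta$sigma, seed = meta$seed)
  if (!identical(prov$stimulus_id, pool_ids(pool)))
    stop("provenance and latent files disagree on stimulus ids", call. = FALSE)
  entries <- lapply(seq_len(nrow(prov)), function(i) {
    structure(list(stimulus_id = prov$stimulus_id[i],
                   latent = pool$codes[[i]],
                   source_ids = strsplit(prov$source_ids[i], ";", fixed = TRUE)[[1L]],
                   noise_seed = as.integer(prov$noise_seed[i])),
              class = "stimulus_entry")
  })
  structure(list(entries = entries, L = pool$L, D = pool$D, config = cfg),
            class = "stimulus_pool")
}

#' Read and write fitted directional models
#'
#' A model is written under a prefix as a latent CSV holding four rows
#' (`target_mean`, `opposite_mean`, `anchor`, `direction`) plus a JSON
#' sidecar `<prefix>_model.json` with participant id, condition labels,
#' selection counts and the fallback flag.
#'
#' @param model a [direction_model()].
#' @param prefix file-path prefix.
#' @return `read_direction_model()`: a [direction_model()].
#' @export
write_direction_model <- function(model, prefix) {
  stopifnot(inherits(model, "direction_model"))
  parts <- c("target_mean", "opposite_mean", "anchor", "direction")
  codes <- lapply(parts, function(p) latent_code(model[[p]]$values, id = p))
  write_latent_pool(latent_pool(codes, metadata = list(kind = "direction_model")),
                    paste0(prefix, "_latents.csv"))
  meta <- list(participant_id = model$participant_id,
               target_label = model$condition$target_label,
               opposite_label = model$condition$opposite_label,
               neither_label = model$condition$neither_label,
               n_target = model$n_target, n_opposite = model$n_opposite,
               n_neither = model$n_neither,
               anchor_is_fallback = model$anchor_is_fallback,
               L = model$L, D = model$D)
  jsonlite::write_json(meta, paste0(prefix, "_model.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_direction_model
#' @export
read_direction_model <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_model.json"), simplifyVector = TRUE)
  pool <- read_latent_pool(paste0(prefix, "_latents.csv"))
  g <- function(nm, id) latent_code(pool$codes[[nm]]$values,
                                    id = paste0(meta$participant_id, ":", id))
  structure(list(participant_id = meta$participant_id,
                 condition = condition_spec(meta$target_label,
                                            meta$opposite_label,
                                            meta$neither_label),
                 target_mean = g("target_mean", "target_mean"),
                 opposite_mean = g("opposite_mean", "opposite_mean"),
                 anchor = g("anchor", "anchor"),
                 direction = g("direction", "direction"),
                 anchor_is_fallback = isTRUE(meta$anchor_is_fallback),
                 n_target = meta$n_target, n_opposite = meta$n_opposite,
                 n_neither = meta$n_neither, L = meta$L, D = meta$D),
            class = "direction_model")
}
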