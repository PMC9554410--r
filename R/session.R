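#' Condition specification for a three-way categorization task
#'
#' Each session belongs to a condition with three response options: the
#' target attribute (e.g. "trustworthy"), its conceptual opposite
#' ("untrustworthy"), and "neither".  The neither option exists to give each
#' participant an unbiased personal starting point in latent space.
#'
#' @param target_label,opposite_label,neither_label three distinct labels.
#' @return Object of class `"condition_spec"`.
#' @export
condition_spec <- function(target_label, opposite_label,
                           neither_label = "neither") {
  labels <- c(target_label, opposite_label, neither_label)
  if (!is.character(labels) || length(labels) != 3L || anyNA(labels))
    stop("labels must be strings", call. = FALSE)
  if (anyDuplicated(labels))
    stop("the three condition labels must be distinct", call. = FALSE)
  structure(list(target_label = target_label, opposite_label = opposite_label,
                 neither_label = neither_label),
            class = "condition_spec")
}

condition_name <- function(condition) {
  paste(condition$target_label, condition$opposite_label, sep = "/")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition: %s / %s / %s>\n", x$target_label,
              x$opposite_label, x$neither_label))
  invisible(x)
}

.responses <- c("target", "opposite", "neither")

#' Construct a categorization session
#'
#' One participant's ordered three-way responses over a stimulus pool.
#' Responses are stored as the canonical categories `"target"`, `"opposite"`,
#' `"neither"`; the condition spec maps them back to attribute labels.
#'
#' @param participant_id participant identifier.
#' @param condition a [condition_spec()].
#' @param trials data frame with columns `trial_index` (unique positive
#'   integers), `stimulus_id` (character) and `response` (one of `"target"`,
#'   `"opposite"`, `"neither"`).
#' @param presentation_order optional character vector of stimulus ids in
#'   presentation order; defaults to the trial order.
#' @return Object of class `"rc_session"`.
#' @export
rc_session <- function(participant_id, condition, trials,
                       presentation_order = NULL) {
  stopifnot(inherits(condition, "condition_spec"))
  if (!is.character(participant_id) || length(participant_id) != 1L)
    stop("participant_id must be a string", call. = FALSE)
  req <- c("trial_index", "stimulus_id", "response")
  if (!is.data.frame(trials) || !all(req %in% names(trials)))
    stop("trials must be a data frame with columns trial_index, stimulus_id, response",
         call. = FALSE)
  trials <- trials[order(trials$trial_index), req, drop = FALSE]
  rownames(trials) <- NULL
  if (anyDuplicated(trials$trial_index))
    stop("trial_index values must be unique within a session", call. = FALSE)
  bad <- setdiff(unique(trials$response), .responses)
  if (length(bad))
    stop(sprintf("unknown response label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(trials$stimulus_id))
    stop("each stimulus may be categorized at most once per session",
         call. = FALSE)
  structure(list(participant_id = participant_id, condition = condition,
                 presentation_order = presentation_order %||% trials$stimulus_id,
                 trials = trials),
            class = "rc_session")
}

#' @export
print.rc_session <- function(x, ...) {
  cnt <- response_counts(x)$counts
  cat(sprintf("<session '%s' (%s): %d trials [%d target / %d opposite / %d neither]>\n",
              x$participant_id, condition_name(x$condition), nrow(x$trials),
              cnt[["target"]], cnt[["opposite"]], cnt[["neither"]]))
  invisible(x)
}

#' Per-category response counts for a session
#'
#' @param session an [rc_session()].
#' @return list with `counts` and `proportions`, each a named numeric vector
#'   over target / opposite / neither, and `n_trials`.  Counts always sum to
#'   the number of trials.
#' @export
response_counts <- function(session) {
  stopifnot(inherits(session, "rc_session"))
  counts <- vapply(.responses,
                   function(r) sum(session$trials$response == r), integer(1))
  n <- nrow(session$trials)
  list(counts = counts,
       proportions = if (n > 0) counts / n else counts * NA_real_,
       n_trials = n)
}

#' Validate a session against a stimulus pool
#'
#' Checks referential integrity instead of raising: unknown stimulus ids,
#' duplicate trial indices or stimulus ids, and (in strict mode) whether
#' every pool stimulus was categorized exactly once.
#'
#' @param session an [rc_session()].
#' @param stimuli a `stimulus_pool` or list of stimulus entries.
#' @param strict if `TRUE`, require complete one-pass coverage of the pool.
#' @return character vector of violations; empty when the session is valid.
#' @export
validate_session <- function(session, stimuli, strict = FALSE) {
  stopifnot(inherits(session, "rc_session"))
  ids <- stimulus_ids(stimuli)
  v <- character(0)
  unknown <- setdiff(session$trials$stimulus_id, ids)
  if (length(unknown))
    v <- c(v, sprintf("unknown stimulus id '%s'", unknown))
  dup_idx <- unique(session$trials$trial_index[duplicated(session$trials$trial_index)])
  if (length(dup_idx))
    v <- c(v, sprintf("duplicated trial_index %d", dup_idx))
  dup_sid <- unique(session$trials$stimulus_id[duplicated(session$trials$stimulus_id)])
  if (length(dup_sid))
    v <- c(v, sprintf("stimulus '%s' categorized more than once", dup_sid))
  if (strict) {
    missing <- setdiff(ids, session$trials$stimulus_id)
    if (length(missing))
      v <- c(v, sprintf("pool stimulus '%s' never categorized", missing))
  }
  v
}

session_csv_header <- c("participant_id", "condition", "target_label",
                        "opposite_label", "trial_index", "stimulus_id",
                        "response")

#' Read and write session CSV files
#'
#' Sessions are stored long-format, one row per trial, with columns
#' `participant_id,condition,target_label,opposite_label,trial_index,
#' stimulus_id,response`.  The round trip is lossless, including presentation
#' order (encoded by `trial_index`).
#'
#' @param sessions list of [rc_session()] objects.
#' @param path CSV file path.
#' @return `read_sessions()`: list of sessions, in first-appearance order of
#'   (participant, condition).
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "rc_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    data.frame(participant_id = s$participant_id,
               condition = condition_name(s$condition),
               target_label = s$condition$target_label,
               opposite_label = s$condition$opposite_label,
               trial_index = s$trials$trial_index,
               stimulus_id = s$trials$stimulus_id,
               response = s$trials$response,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    as.data.frame(stats::setNames(rep(list(character(0)), 7),
                                  session_csv_header))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trial_index = "integer"))
  if (!all(session_csv_header %in% names(df)))
    stop(sprintf("session file missing column(s): %s",
                 paste(setdiff(session_csv_header, names(df)), collapse = ", ")),
         call. = FALSE)
  if (nrow(df) == 0L) return(list())
  # +1 for the header row: report the file line, not the data-frame row.
  bad_resp <- which(!df$response %in% .responses)
  if (length(bad_resp))
    stop(sprintf("line %d: unknown response label '%s'",
                 bad_resp[1L] + 1L, df$response[bad_resp[1L]]), call. = FALSE)
  bad_idx <- which(is.na(df$trial_index) | df$trial_index < 1)
  if (length(bad_idx))
    stop(sprintf("line %d: malformed trial_index", bad_idx[1L] + 1L),
         call. = FALSE)
  key <- paste(df$participant_id, df$condition, sep = "\r")
  lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    cond <- condition_spec(sub$target_label[1L], sub$opposite_label[1L])
    rc_session(sub$participant_id[1L], cond,
               sub[, c("trial_index", "stimulus_id", "response")])
  })
}
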