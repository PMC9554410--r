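#' Ratings tables
#'
#' Cross-classified ratings: every participant rates every stimulus,
#' `r` times each.  Used to partition judgment variance into shared
#' (stimulus) and idiosyncratic (participant, participant-by-stimulus)
#' components.
#'
#' @param df data frame with columns `participant_id`, `stimulus_id`,
#'   `repetition` (1-based integer) and `rating` (numeric).
#' @return The validated data frame with class `"ratings_table"` prepended.
#' @export
as_ratings_table <- function(df) {
  req <- c("participant_id", "stimulus_id", "repetition", "rating")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("ratings table needs columns participant_id, stimulus_id, repetition, rating",
         call. = FALSE)
  df <- as.data.frame(df)[, req]
  if (!is.numeric(df$rating) || anyNA(df$rating))
    stop("ratings must be numeric and non-missing", call. = FALSE)
  if (!is.numeric(df$repetition) || any(df$repetition < 1))
    stop("repetition must be a 1-based integer", call. = FALSE)
  if (anyDuplicated(df[, c("participant_id", "stimulus_id", "repetition")]))
    stop("duplicate (participant, stimulus, repetition) rows", call. = FALSE)
  class(df) <- c("ratings_table", "data.frame")
  df
}

ratings_design <- function(tbl) {
  p_ids <- unique(tbl$participant_id)
  s_ids <- unique(tbl$stimulus_id)
  cnt <- table(factor(tbl$participant_id, p_ids),
               factor(tbl$stimulus_id, s_ids))
  list(p_ids = p_ids, s_ids = s_ids, cell_counts = cnt,
       balanced = length(unique(as.vector(cnt))) == 1L && all(cnt > 0))
}

#' Two-way crossed random-effects mean squares
#'
#' Classical balanced two-way ANOVA with replication for the rating model
#' \deqn{y_{ijk} = \mu + a_i + b_j + (ab)_{ij} + e_{ijk}}
#' (participant `i`, stimulus `j`, repetition `k`): sums of squares for
#' participants, stimuli, their interaction and the within-cell error, each
#' divided by its degrees of freedom (`p-1`, `s-1`, `(p-1)(s-1)`,
#' `p*s*(r-1)`).
#'
#' @param table a [as_ratings_table()] (or coercible data frame); must be a
#'   complete balanced `p x s x r` design with `r >= 2`.
#' @return list with `MS_P`, `MS_S`, `MS_PS`, `MS_E`, matching `SS_*` and
#'   `df_*`, and `design = c(p, s, r)`.
#' @export
anova_mean_squares <- function(table) {
  tbl <- as_ratings_table(table)
  des <- ratings_design(tbl)
  if (!des$balanced)
    stop("unbalanced ratings table: use balanced_subset() first", call. = FALSE)
  p <- length(des$p_ids); s <- length(des$s_ids)
  r <- as.integer(des$cell_counts[1L, 1L])
  if (r < 2L)
    stop("r = 1: interaction and residual not separable", call. = FALSE)

  pf <- factor(tbl$participant_id, des$p_ids)
  sf <- factor(tbl$stimulus_id, des$s_ids)
  y <- tbl$rating
  grand <- mean(y)
  m_p <- tapply(y, pf, mean)
  m_s <- tapply(y, sf, mean)
  m_cell <- tapply(y, list(pf, sf), mean)

  SS_P <- s * r * sum((m_p - grand)^2)
  SS_S <- p * r * sum((m_s - grand)^2)
  SS_PS <- r * sum((m_cell - outer(m_p, rep(1, s)) -
                      outer(rep(1, p), m_s) + grand)^2)
  SS_E <- sum((y - m_cell[cbind(pf, sf)])^2)

  list(MS_P = SS_P / (p - 1), MS_S = SS_S / (s - 1),
       MS_PS = SS_PS / ((p - 1) * (s - 1)), MS_E = SS_E / (p * s * (r - 1)),
       SS_P = SS_P, SS_S = SS_S, SS_PS = SS_PS, SS_E = SS_E,
       df_P = p - 1, df_S = s - 1, df_PS = (p - 1) * (s - 1),
       df_E = p * s * (r - 1), design = c(p = p, s = s, r = r))
}

#' Partition rating variance into shared and idiosyncratic components
#'
#' Method-of-moments variance components from the expected mean squares of
#' the balanced two-way crossed random-effects layout:
#' \deqn{\hat\sigma^2_e = MS_E,\quad
#'       \hat\sigma^2_{ps} = (MS_{PS} - MS_E)/r,\quad
#'       \hat\sigma^2_s = (MS_S - MS_{PS})/(p\,r),\quad
#'       \hat\sigma^2_p = (MS_P - MS_{PS})/(s\,r),}
#' with negative estimates truncated to zero before normalization.  Reported
#' as raw components plus two proportion scales: `vpc_total` (share of total
#' observed variance, four components) and `vpc_reliable` (share of the
#' non-residual, "reliable" variance over participant / stimulus /
#' interaction).  The stimulus component is the shared part of judgment
#' variance; participant and participant-by-stimulus are idiosyncratic.
#'
#' With `r = 1` a reduced decomposition is returned: interaction and
#' residual are confounded into one component (labelled), and
#' `vpc_reliable` is `NA`.
#'
#' @param table a ratings table (see [as_ratings_table()]), balanced.
#' @return Object of class `"vpc"`: list with `components` (named variances),
#'   `vpc_total`, `vpc_reliable`, `mean_squares`, `design`, `reduced`,
#'   `estimator`.
#' @examples
#' tab <- simulate_ratings(vpc_truth(3, 0.1, 0.6, 0.2, 0.1),
#'                         p = 30, s = 40, r = 2, seed = 11)
#' vpc(tab)
#' @export
vpc <- function(table) {
  tbl <- as_ratings_table(table)
  des <- ratings_design(tbl)
  if (!des$balanced)
    stop("unbalanced ratings table: use balanced_subset() first", call. = FALSE)
  r <- as.integer(des$cell_counts[1L, 1L])

  if (r >= 2L) {
    ms <- anova_mean_squares(tbl)
    p <- ms$design["p"]; s <- ms$design["s"]
    sigma2_e <- ms$MS_E
    sigma2_ps <- max(0, (ms$MS_PS - ms$MS_E) / r)
    sigma2_s <- max(0, (ms$MS_S - ms$MS_PS) / (p * r))
    sigma2_p <- max(0, (ms$MS_P - ms$MS_PS) / (s * r))
    comp <- c(participant = unname(sigma2_p), stimulus = unname(sigma2_s),
              interaction = unname(sigma2_ps), residual = unname(sigma2_e))
    tot <- sum(comp)
    vpc_total <- if (tot > 0) comp / tot else comp * NA_real_
    rel <- comp[c("participant", "stimulus", "interaction")]
    vpc_reliable <- if (sum(rel) > 0) rel / sum(rel) else rel * NA_real_
    reduced <- FALSE
  } else {
    # r = 1: within-cell replication absent; interaction and residual merge.
    p <- length(des$p_ids); s <- length(des$s_ids)
    pf <- factor(tbl$participant_id, des$p_ids)
    sf <- factor(tbl$stimulus_id, des$s_ids)
    y <- tbl$rating
    grand <- mean(y)
    m_p <- tapply(y, pf, mean); m_s <- tapply(y, sf, mean)
    MS_P <- s * sum((m_p - grand)^2) / (p - 1)
    MS_S <- p * sum((m_s - grand)^2) / (s - 1)
    resid <- y - m_p[pf] - m_s[sf] + grand
    MS_PS <- sum(resid^2) / ((p - 1) * (s - 1))
    comp <- c(participant = max(0, (MS_P - MS_PS) / s),
              stimulus = max(0, (MS_S - MS_PS) / p),
              interaction_plus_residual = unname(MS_PS))
    tot <- sum(comp)
    vpc_total <- if (tot > 0) comp / tot else comp * NA_real_
    vpc_reliable <- NA
    ms <- list(MS_P = MS_P, MS_S = MS_S, MS_PS = MS_PS,
               design = c(p = p, s = s, r = 1L))
    reduced <- TRUE
  }

  structure(list(components = comp, vpc_total = vpc_total,
                 vpc_reliable = vpc_reliable, mean_squares = ms,
                 design = ms$design, reduced = reduced,
                 estimator = "expected-mean-squares method of moments (balanced two-way crossed random effects)"),
            class = "vpc")
}

#' @export
print.vpc <- function(x, digits = 3, ...) {
  cat("Variance partitioning (", paste(sprintf("%s=%d", names(x$design),
                                               x$design), collapse = ", "),
      ")\n", sep = "")
  if (x$reduced)
    cat("  [reduced decomposition: r = 1, interaction and residual confounded]\n")
  tab <- cbind(variance = x$components, `share of total` = x$vpc_total)
  if (!x$reduced && !anyNA(x$vpc_reliable))
    tab <- cbind(tab, `share of reliable` =
                   c(x$vpc_reliable, residual = NA)[rownames(tab)])
  print(round(tab, digits))
  cat("  estimator:", x$estimator, "\n")
  invisible(x)
}

#' @export
summary.vpc <- function(object, ...) {
  shared <- if (object$reduced) unname(object$vpc_total["stimulus"])
            else unname(object$vpc_reliable["stimulus"])
  out <- c(object, list(shared_reliable = shared))
  class(out) <- c("summary.vpc", "vpc")
  out
}

#' @export
print.summary.vpc <- function(x, ...) {
  NextMethod()
  if (is.finite(x$shared_reliable))
    cat(sprintf("  shared (stimulus) share of reliable variance: %.1f%%\n",
                100 * x$shared_reliable))
  invisible(x)
}

#' Largest balanced sub-table of a ratings table
#'
#' Greedy completion: repeatedly drop participants that do not cover every
#' retained stimulus and stimuli not covered by every retained participant,
#' then truncate repetitions to the common per-cell minimum.
#'
#' @param table a ratings table.
#' @return A balanced `ratings_table`; attributes `dropped_participants`,
#'   `dropped_stimuli` and `r` report what was removed.
#' @export
balanced_subset <- function(table) {
  tbl <- as_ratings_table(table)
  p_keep <- unique(tbl$participant_id)
  s_keep <- unique(tbl$stimulus_id)
  repeat {
    sub <- tbl[tbl$participant_id %in% p_keep & tbl$stimulus_id %in% s_keep, ]
    cnt <- table(factor(sub$participant_id, p_keep),
                 factor(sub$stimulus_id, s_keep))
    bad_p <- p_keep[rowSums(cnt == 0) > 0]
    if (length(bad_p)) { p_keep <- setdiff(p_keep, bad_p); next }
    bad_s <- s_keep[colSums(cnt == 0) > 0]
    if (length(bad_s)) { s_keep <- setdiff(s_keep, bad_s); next }
    break
  }
  if (!length(p_keep) || !length(s_keep))
    stop("no balanced sub-table exists", call. = FALSE)
  sub <- tbl[tbl$participant_id %in% p_keep & tbl$stimulus_id %in% s_keep, ]
  r <- min(table(sub$participant_id, sub$stimulus_id))
  sub <- sub[order(sub$participant_id, sub$stimulus_id, sub$repetition), ]
  keep <- unlist(lapply(split(seq_len(nrow(sub)),
                              paste(sub$participant_id, sub$stimulus_id,
                                    sep = "\r")),
                        function(i) i[seq_len(r)]), use.names = FALSE)
  out <- sub[sort(keep), ]
  # renumber repetitions 1..r within each cell
  out$repetition <- stats::ave(out$repetition, out$participant_id,
                               out$stimulus_id, FUN = seq_along)
  rownames(out) <- NULL
  out <- as_ratings_table(out)
  attr(out, "dropped_participants") <- setdiff(unique(tbl$participant_id), p_keep)
  attr(out, "dropped_stimuli") <- setdiff(unique(tbl$stimulus_id), s_keep)
  attr(out, "r") <- as.integer(r)
  out
}

#' Read and write ratings CSV files
#'
#' Plain CSV with columns `participant_id,stimulus_id,repetition,rating`;
#' ratings are written at full decimal precision so the round trip is exact.
#'
#' @param table a ratings table.
#' @param path CSV file path.
#' @return `read_ratings()`: a `ratings_table`.
#' @export
write_ratings <- function(table, path) {
  tbl <- as_ratings_table(table)
  out <- data.frame(participant_id = tbl$participant_id,
                    stimulus_id = tbl$stimulus_id,
                    repetition = as.integer(tbl$repetition),
                    rating = format_full(tbl$rating))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       stimulus_id = "character",
                                       repetition = "integer",
                                       rating = "numeric"))
  as_ratings_table(df)
}
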