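# Independent brute-force oracles.  These deliberately use explicit loops
# and never call the package's own estimators, so that agreement between the
# two routes is meaningful.

# Category means and direction by explicit summation over trials.
oracle_direction <- function(session, entries) {
  lat <- lapply(entries, function(e) e$latent$values)
  names(lat) <- vapply(entries, function(e) e$stimulus_id, "")
  sums <- list(target = NULL, opposite = NULL, neither = NULL)
  counts <- c(target = 0, opposite = 0, neither = 0)
  for (i in seq_len(nrow(session$trials))) {
    resp <- session$trials$response[i]
    m <- lat[[session$trials$stimulus_id[i]]]
    if (is.null(sums[[resp]])) sums[[resp]] <- m * 0
    sums[[resp]] <- sums[[resp]] + m
    counts[resp] <- counts[resp] + 1
  }
  tm <- sums$target / counts["target"]
  om <- sums$opposite / counts["opposite"]
  list(target_mean = tm, opposite_mean = om, direction = tm - om,
       anchor = if (counts["neither"] > 0) sums$neither / counts["neither"],
       counts = counts)
}

# Two-way crossed ANOVA sums of squares by explicit loops.
oracle_mean_squares <- function(tbl) {
  p_ids <- unique(tbl$participant_id)
  s_ids <- unique(tbl$stimulus_id)
  p <- length(p_ids); s <- length(s_ids)
  r <- nrow(tbl) / (p * s)
  grand <- mean(tbl$rating)
  cell <- function(i, j) tbl$rating[tbl$participant_id == p_ids[i] &
                                      tbl$stimulus_id == s_ids[j]]
  m_p <- sapply(p_ids, function(pi) mean(tbl$rating[tbl$participant_id == pi]))
  m_s <- sapply(s_ids, function(si) mean(tbl$rating[tbl$stimulus_id == si]))
  SS_P <- 0; SS_S <- 0; SS_PS <- 0; SS_E <- 0
  for (i in seq_len(p)) SS_P <- SS_P + s * r * (m_p[i] - grand)^2
  for (j in seq_len(s)) SS_S <- SS_S + p * r * (m_s[j] - grand)^2
  for (i in seq_len(p)) for (j in seq_len(s)) {
    yc <- cell(i, j)
    mc <- mean(yc)
    SS_PS <- SS_PS + r * (mc - m_p[i] - m_s[j] + grand)^2
    for (y in yc) SS_E <- SS_E + (y - mc)^2
  }
  list(MS_P = SS_P / (p - 1), MS_S = SS_S / (s - 1),
       MS_PS = SS_PS / ((p - 1) * (s - 1)), MS_E = SS_E / (p * s * (r - 1)),
       p = p, s = s, r = r)
}

# Method-of-moments components from oracle mean squares.
oracle_components <- function(tbl) {
  ms <- oracle_mean_squares(tbl)
  c(participant = max(0, (ms$MS_P - ms$MS_PS) / (ms$s * ms$r)),
    stimulus = max(0, (ms$MS_S - ms$MS_PS) / (ms$p * ms$r)),
    interaction = max(0, (ms$MS_PS - ms$MS_E) / ms$r),
    residual = ms$MS_E)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
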