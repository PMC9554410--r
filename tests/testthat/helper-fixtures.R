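# Small in-code fixtures used across test files.

toy_code <- function(values, id = "x") {
  latent_code(matrix(values[[1]], nrow = length(values),
                     ncol = length(values[[1]]), byrow = TRUE,
                     dimnames = NULL), id)
}

# Build stimulus entries directly from a list of latent matrices.
make_entries <- function(mats, ids = sprintf("s%04d", seq_along(mats))) {
  lapply(seq_along(mats), function(i) {
    structure(list(stimulus_id = ids[i],
                   latent = latent_code(mats[[i]], ids[i]),
                   source_ids = "src", noise_seed = 0L),
              class = "stimulus_entry")
  })
}

make_session <- function(responses, ids = sprintf("s%04d", seq_along(responses)),
                         participant = "p1",
                         condition = condition_spec("trustworthy",
                                                    "untrustworthy")) {
  rc_session(participant, condition,
             data.frame(trial_index = seq_along(responses),
                        stimulus_id = ids, response = responses,
                        stringsAsFactors = FALSE))
}

# Random toy session + stimuli for oracle comparisons.
random_toy_case <- function(seed, n_stim = 12, L = 3, D = 4) {
  set.seed(seed)
  mats <- replicate(n_stim, matrix(rnorm(L * D), L, D), simplify = FALSE)
  entries <- make_entries(mats)
  repeat {
    resp <- sample(c("target", "opposite", "neither"), n_stim, replace = TRUE)
    if (any(resp == "target") && any(resp == "opposite")) break
  }
  list(entries = entries, session = make_session(resp), mats = mats,
       resp = resp)
}

# Balanced random ratings table for ANOVA oracle comparisons.
random_ratings <- function(seed, p = 3, s = 4, r = 2) {
  set.seed(seed)
  g <- expand.grid(repetition = seq_len(r),
                   stimulus_id = sprintf("s%02d", seq_len(s)),
                   participant_id = sprintf("p%02d", seq_len(p)),
                   stringsAsFactors = FALSE)
  g$rating <- rnorm(nrow(g))
  as_ratings_table(g)
}
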