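test_that("synthetic latent pools have the planted structure", {
  pool <- simulate_latent_pool(n_faces = 40, L = 3, D = 8, n_factors = 2,
                               seed = 5)
  expect_equal(length(pool), 40)
  expect_equal(dim(pool$codes[[1]]$values), c(3, 8))

  # factors are orthonormal
  f <- pool$metadata$factors
  expect_equal(t(f) %*% f, diag(2), tolerance = 1e-12)

  # bit reproducibility
  pool2 <- simulate_latent_pool(n_faces = 40, L = 3, D = 8, n_factors = 2,
                                seed = 5)
  expect_identical(pool_matrix(pool), pool_matrix(pool2))
  pool3 <- simulate_latent_pool(n_faces = 40, L = 3, D = 8, n_factors = 2,
                                seed = 6)
  expect_false(identical(pool_matrix(pool), pool_matrix(pool3)))

  # noiseless single-factor pools are collinear about the mean
  lin <- simulate_latent_pool(n_faces = 10, L = 2, D = 6, n_factors = 1,
                              noise_scale = 0, seed = 1)
  m <- pool_matrix(lin)
  expect_equal(qr(m)$rank, 1)

  expect_error(simulate_latent_pool(10, L = 2, D = 2, n_factors = 5),
               "n_factors")
})

test_that("observer directions interpolate between shared and idiosyncratic", {
  shared <- rnorm(50)
  obs1 <- make_observers(shared, n = 4, w = 1, seed = 2)
  for (o in obs1) {
    expect_equal(sum(o$true_direction^2), 1, tolerance = 1e-9)
    expect_equal(o$true_direction, shared / sqrt(sum(shared^2)),
                 tolerance = 1e-12)
  }

  mean_cos <- function(w, seed, dim = 400) {
    obs <- make_observers(rnorm(dim), n = 6, w = w, seed = seed)
    dirs <- sapply(obs, `[[`, "true_direction")
    cm <- crossprod(dirs)
    mean(cm[upper.tri(cm)])
  }
  # w = 0: near-orthogonal in high dimension
  expect_lt(abs(mean_cos(0, seed = 3)), 0.2)

  # w = 0.9 cosines exceed w = 0.3 cosines in >= 95% of replicates
  wins <- sapply(1:20, function(s) mean_cos(0.9, s) > mean_cos(0.3, s))
  expect_gte(mean(wins), 0.95)

  expect_error(make_observers(shared, n = 0, w = 0.5), ">= 1")
  expect_error(make_observers(shared, n = 2, w = 1.5), "\\[0, 1\\]")
})

test_that("simulated sessions follow the threshold decision rule", {
  pool <- simulate_latent_pool(n_faces = 30, L = 2, D = 10, n_factors = 2,
                               seed = 7)
  sp <- generate_stimulus_pool(pool, stimulus_config(25, 5, sigma = 0.2,
                                                     seed = 3))
  anchor <- unflatten_latent(colMeans(stimulus_matrix(sp)), 2, 10, "gm")
  cond <- condition_spec("trustworthy", "untrustworthy")
  obs <- make_observers(pool$metadata$factors[, 1], n = 1, w = 1,
                        tau = 1e12, seed = 4)[[1]]

  # tau = infinity-like: everything lands in "neither"
  sess <- simulate_session(obs, sp, anchor, cond, seed = 5)
  expect_equal(unname(response_counts(sess)$counts[["neither"]]), 25)

  # strict validation: each stimulus categorized exactly once
  expect_length(validate_session(sess, sp, strict = TRUE), 0)

  # constructed stimulus along the direction -> "target"
  obs0 <- make_observers(pool$metadata$factors[, 1], n = 1, w = 1, tau = 0,
                         seed = 4)[[1]]
  along <- make_entries(list(matrix(flatten_latent(anchor) +
                                      3 * obs0$true_direction,
                                    2, 10, byrow = TRUE),
                             matrix(flatten_latent(anchor) -
                                      3 * obs0$true_direction,
                                    2, 10, byrow = TRUE)))
  s2 <- simulate_session(obs0, along, anchor, cond, seed = 1)
  resp <- s2$trials$response[order(s2$trials$stimulus_id)]
  expect_equal(resp, c("target", "opposite"))

  # bit reproducibility and seed sensitivity of presentation order
  sess_a <- simulate_session(obs0, sp, anchor, cond, seed = 11)
  sess_b <- simulate_session(obs0, sp, anchor, cond, seed = 11)
  expect_identical(sess_a, sess_b)
  sess_c <- simulate_session(obs0, sp, anchor, cond, seed = 12)
  expect_false(identical(sess_a$presentation_order,
                         sess_c$presentation_order))
})

test_that("lapses randomize the configured fraction of responses", {
  pool <- simulate_latent_pool(n_faces = 50, L = 2, D = 12, seed = 2)
  sp <- generate_stimulus_pool(pool, stimulus_config(200, 5, sigma = 0.2,
                                                     seed = 3))
  anchor <- unflatten_latent(colMeans(stimulus_matrix(sp)), 2, 12, "gm")
  cond <- condition_spec("a", "b")
  base <- make_observers(pool$metadata$factors[, 1], 1, w = 1, tau = 1e12,
                         lapse = 0.5, seed = 4)[[1]]
  sess <- simulate_session(base, sp, anchor, cond, seed = 6)
  cnt <- response_counts(sess)$counts
  # without lapses all 200 would be "neither"; ~1/3 of lapsed trials return there
  n_lapsed_visible <- cnt[["target"]] + cnt[["opposite"]]
  expect_gt(n_lapsed_visible, 200 * 0.5 * 2 / 3 - 30)
  expect_lt(n_lapsed_visible, 200 * 0.5 * 2 / 3 + 30)
})

test_that("simulated ratings realize the generative ANOVA model", {
  # all variances zero is rejected; near-zero residual only -> constant mu
  expect_error(vpc_truth(3, 0, 0, 0, 0), "positive")

  t_stim <- vpc_truth(10, 0, 1, 0, 0)
  tab <- simulate_ratings(t_stim, p = 4, s = 6, r = 3, seed = 9)
  expect_equal(nrow(tab), 4 * 6 * 3)
  # stimulus-only variance: constant within stimulus across participants/reps
  spread <- tapply(tab$rating, tab$stimulus_id, function(z) diff(range(z)))
  expect_true(all(spread == 0))
  expect_gt(diff(range(tab$rating)), 0)

  expect_identical(simulate_ratings(t_stim, 3, 3, 2, seed = 1),
                   simulate_ratings(t_stim, 3, 3, 2, seed = 1))
  expect_error(simulate_ratings(t_stim, 1, 3, 2, seed = 1), "invalid design")
})

test_that("the pipeline recovers a planted direction and degrades with lapse", {
  pool <- simulate_latent_pool(n_faces = 80, L = 4, D = 32, n_factors = 4,
                               seed = 13)
  sp <- generate_stimulus_pool(pool, stimulus_config(120, 10, sigma = 0.4,
                                                     seed = 14))
  anchor <- unflatten_latent(colMeans(stimulus_matrix(sp)), 4, 32, "gm")
  cond <- condition_spec("t", "u")
  truth_dir <- pool$metadata$factors[, 1]

  rec <- function(lapse, seed) {
    obs <- make_observers(truth_dir, 1, w = 1, tau = 0, lapse = lapse,
                          seed = seed)[[1]]
    sess <- simulate_session(obs, sp, anchor, cond, seed = seed + 1000)
    fit <- direction_model(sess, sp, seed = seed + 2000)
    cosine(as.vector(t(coef(fit))), truth_dir)
  }
  cos0 <- sapply(1:8, rec, lapse = 0)
  cos5 <- sapply(1:8, rec, lapse = 0.5)
  expect_gt(mean(cos0), 0.5)
  expect_gt(mean(cos0), mean(cos5))
})
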