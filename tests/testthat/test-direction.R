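test_that("fitted means and direction match brute-force summation exactly", {
  for (seed in 1:20) {
    case <- random_toy_case(seed)
    fit <- direction_model(case$session, case$entries, seed = seed)
    oracle <- oracle_direction(case$session, case$entries)
    expect_identical(fit$target_mean$values, oracle$target_mean)
    expect_identical(fit$opposite_mean$values, oracle$opposite_mean)
    expect_identical(fit$direction$values, oracle$direction)
    expect_identical(fit$direction$values,
                     fit$target_mean$values - fit$opposite_mean$values)
    if (!is.null(oracle$anchor))
      expect_identical(fit$anchor$values, oracle$anchor)
    expect_equal(c(fit$n_target, fit$n_opposite, fit$n_neither),
                 unname(oracle$counts))
  }
})

test_that("hand-computed toy directions are reproduced", {
  mats <- list(matrix(c(2, 2), 1, 2), matrix(c(4, 0), 1, 2),
               matrix(c(0, 0), 1, 2), matrix(c(2, 2), 1, 2),
               matrix(c(9, 9), 1, 2))
  entries <- make_entries(mats)
  s <- make_session(c("target", "target", "opposite", "opposite", "neither"))
  fit <- direction_model(s, entries)
  expect_equal(fit$direction$values, matrix(c(2, 0), 1, 2))  # (3,1)-(1,1)
  expect_equal(fit$anchor$values, matrix(c(9, 9), 1, 2))
  expect_false(fit$anchor_is_fallback)

  # target set = opposite set -> zero direction
  s0 <- make_session(c("target", "opposite", "neither"),
                     ids = c("s0001", "s0002", "s0003"))
  e0 <- make_entries(list(matrix(c(1, 2), 1, 2), matrix(c(1, 2), 1, 2),
                          matrix(0, 1, 2)))
  fit0 <- direction_model(s0, e0)
  expect_equal(fit0$direction$values, matrix(0, 1, 2))
})

test_that("degenerate sessions are rejected", {
  entries <- make_entries(replicate(4, matrix(rnorm(4), 2, 2),
                                    simplify = FALSE))
  all_target <- make_session(rep("target", 4))
  expect_error(direction_model(all_target, entries, seed = 1),
               "degenerate session: direction undefined")
  no_opp <- make_session(c("target", "target", "neither", "neither"))
  expect_error(direction_model(no_opp, entries, seed = 1),
               "degenerate session")
})

test_that("anchor fallback samples the pool but never moves the direction", {
  set.seed(99)
  entries <- make_entries(replicate(30, matrix(rnorm(6), 2, 3),
                                    simplify = FALSE))
  s <- make_session(sample(c("target", "opposite"), 30, replace = TRUE))
  fit1 <- direction_model(s, entries, fallback_n = 20, seed = 1)
  fit2 <- direction_model(s, entries, fallback_n = 20, seed = 2)
  expect_true(fit1$anchor_is_fallback)
  expect_false(identical(fit1$anchor$values, fit2$anchor$values))
  expect_identical(fit1$direction$values, fit2$direction$values)
  expect_error(direction_model(s, entries), "seed")

  # fallback anchor is the mean of a 20-stimulus subset: verify it lies in
  # the convex hull bounds of the pool
  rng <- range(vapply(entries, function(e) e$latent$values[1, 1], 0))
  expect_gte(fit1$anchor$values[1, 1], rng[1])
  expect_lte(fit1$anchor$values[1, 1], rng[2])
})

test_that("extrapolation is exactly linear in C", {
  case <- random_toy_case(7)
  fit <- direction_model(case$session, case$entries, seed = 1)

  expect_identical(extrapolate(fit, 0)$values, fit$anchor$values)   # M_0 = N
  expect_identical(extrapolate(fit, 1)$values,
                   fit$anchor$values + fit$direction$values)        # M_1
  for (C in c(-8, -3.5, 0.25, 2, 8)) {
    expect_identical(extrapolate(fit, C)$values,
                     fit$anchor$values + C * fit$direction$values)
    # M_{2C} - N = 2 (M_C - N), machine precision (doubling past the
    # rendering-range warning is intentional here)
    expect_equal(suppressWarnings(extrapolate(fit, 2 * C))$values -
                   fit$anchor$values,
                 2 * (extrapolate(fit, C)$values - fit$anchor$values),
                 tolerance = 1e-15)
  }

  # hand example: anchor [[1,1]], direction [[2,0]], C = -8 -> [[-15, 1]]
  hand <- structure(list(participant_id = "h",
                         condition = condition_spec("a", "b"),
                         anchor = latent_code(matrix(c(1, 1), 1, 2), "n"),
                         direction = latent_code(matrix(c(2, 0), 1, 2), "d"),
                         L = 1L, D = 2L),
                    class = "direction_model")
  expect_equal(extrapolate(hand, -8)$values, matrix(c(-15, 1), 1, 2))

  expect_warning(extrapolate(fit, 9), "exceeds 8")
  expect_error(extrapolate(fit, Inf), "finite")
  expect_error(extrapolate(fit, NA_real_), "finite")
})

test_that("representation series follows the default intensity ladder", {
  case <- random_toy_case(3)
  fit <- direction_model(case$session, case$entries, seed = 2)
  series <- representation_series(fit)
  expect_length(series$latents, 9)
  expect_identical(series$latents[[5]]$values, fit$anchor$values)  # C = 0
  expect_equal(series$visibility_threshold, 4)

  # symmetry: M_{-c} and M_{+c} average to the anchor
  pair <- representation_series(fit, c(-3, 3))
  expect_equal((pair$latents[[1]]$values + pair$latents[[2]]$values) / 2,
               fit$anchor$values, tolerance = 1e-12)

  # zero direction: all members equal the anchor
  fit0 <- fit
  fit0$direction <- latent_code(0 * fit$direction$values, "zero")
  s0 <- representation_series(fit0, c(-8, 0, 8))
  for (lat in s0$latents) expect_equal(lat$values, fit$anchor$values)

  expect_error(representation_series(fit, numeric(0)), "non-empty")

  # predict() mirrors extrapolate/series
  expect_identical(predict(fit, 2)$values, extrapolate(fit, 2)$values)
  expect_length(predict(fit)$latents, 9)
  expect_identical(coef(fit), fit$direction$values)
})

test_that("latent_pearson matches closed-form Pearson on flattened matrices", {
  a <- latent_code(matrix(c(1, 3, 2, 4), 2, 2), "a")   # flat: 1 2 3 4
  rev <- latent_code(matrix(c(4, 2, 3, 1), 2, 2), "r") # flat: 4 3 2 1
  expect_equal(latent_pearson(a, a), 1.0)
  expect_equal(latent_pearson(a, rev), -1.0)

  # affine invariance
  shifted <- latent_code(2 * a$values + 7, "s")
  expect_equal(latent_pearson(a, shifted), 1.0)

  flat <- latent_code(matrix(5, 2, 2), "flat")
  expect_error(latent_pearson(a, flat), "undefined correlation")
  b <- latent_code(matrix(1, 3, 3), "b")
  expect_error(latent_pearson(a, b), "heterogeneous shapes")

  # per-layer variant averages row-wise correlations
  set.seed(1)
  x <- latent_code(matrix(rnorm(12), 3, 4), "x")
  y <- latent_code(matrix(rnorm(12), 3, 4), "y")
  manual <- mean(sapply(1:3, function(i) cor(x$values[i, ], y$values[i, ])))
  expect_equal(latent_pearson(x, y, method = "per_layer"), manual)
})

test_that("pairwise agreement behaves at the constructed extremes", {
  case <- random_toy_case(11)
  fit <- direction_model(case$session, case$entries, seed = 1)

  five <- replicate(5, fit, simplify = FALSE)
  ag <- pairwise_agreement(five, C = 8)
  expect_equal(ag$mean_r, 1.0)
  expect_true(all(ag$pairs == 1))
  expect_equal(ag$n_pairs, 10)

  # antipodal directions with shared zero anchor -> r = -1 at any C != 0
  zero <- latent_code(matrix(0, 2, 3), "z")
  d <- latent_code(matrix(rnorm(6), 2, 3), "d")
  mk <- function(id, dir) structure(
    list(participant_id = id, condition = condition_spec("a", "b"),
         anchor = zero, direction = dir, L = 2L, D = 3L),
    class = "direction_model")
  anti <- list(mk("m1", d), mk("m2", latent_code(-d$values, "nd")))
  expect_equal(pairwise_agreement(anti, C = 4)$mean_r, -1.0)

  expect_error(pairwise_agreement(list(fit), C = 8), "at least two")

  # direction-only variant ignores the anchor
  ag_dir <- pairwise_agreement(anti, C = 4, include_anchor = FALSE)
  expect_equal(ag_dir$mean_r, -1.0)
})
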