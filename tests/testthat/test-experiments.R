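test_that("overlap_R matches hand arithmetic", {
  expect_equal(overlap_R(c(1.5, 0.5), c(0.5, 1.5)), -1)
  expect_equal(overlap_R(c(0.3, 0.7), c(0.3, 0.7)), 1)
  # shifted-orthogonal vectors
  expect_equal(overlap_R(c(1.5, 1), c(1, 1.5)), 0)
  expect_error(overlap_R(c(1, 1), c(0.5, 1.5)), "zero norm")
  expect_error(overlap_R(1:3, 1:2), "same length")
})

test_that("eps_from_overlap is the arccos map and is monotone", {
  expect_equal(eps_from_overlap(1), 0)
  expect_equal(eps_from_overlap(0), 0.5)
  expect_equal(eps_from_overlap(-1), 1)
  r <- seq(-1, 1, length.out = 41)
  expect_true(all(diff(eps_from_overlap(r)) < 0))
  expect_equal(eps_from_overlap(1 + 1e-13), 0)   # clamped within tolerance
  expect_error(eps_from_overlap(1.01), "\\[-1, 1\\]")
})

test_that("detect_frozen applies the variance criterion over 500 inputs", {
  expect_true(detect_frozen(rep(1, 500)))
  expect_false(detect_frozen(rep(c(1.0, 1.2), 250)))   # variance ~ 0.01
  step <- c(rep(1, 250), rep(1 + 1e-3, 250))           # variance ~ 2.5e-7
  expect_true(detect_frozen(step))
  expect_true(is.na(detect_frozen(rep(1, 499))))
  # only the last 500 values count
  expect_true(detect_frozen(c(rep(9, 100), rep(1, 500))))
})

test_that("generalization error is the mismatch fraction", {
  # identical pair: exactly zero, no sampling noise possible
  set.seed(701)
  t <- synaptic_perceptron(40)
  pair <- teacher_student_pair(t, t)
  res <- generalization_error(pair, eval_schedule(n_test = 20))
  expect_identical(res$eps_g, 0)
  expect_identical(res$stderr, 0)
  # teacher always fires, student never can: every stimulation mismatches
  th <- synaptic_perceptron(40, weights = rep(1.3, 40))
  sl <- synaptic_perceptron(40, weights = rep(1e-4, 40))
  pair2 <- teacher_student_pair(th, sl)
  res2 <- generalization_error(pair2, eval_schedule(n_test = 20))
  expect_equal(res2$eps_g, 1)
})

test_that("weight firing threshold is threshold over minimal amplitude", {
  expect_equal(weight_firing_threshold(), 1.25)
  expect_equal(weight_firing_threshold(lif_params(v_threshold = 1), 0.5), 2)
})

test_that("fit_power_exponent recovers known exponents", {
  p <- seq(1000, 20000, by = 1000)
  exact <- data.frame(p = p, eps_g = p^-1)
  f1 <- fit_power_exponent(exact, range(p))
  expect_equal(f1$exponent, 1, tolerance = 1e-10)
  expect_equal(f1$goodness, 1, tolerance = 1e-10)
  # scale invariance
  scaled <- data.frame(p = p, eps_g = 7.3 * p^-2)
  expect_equal(fit_power_exponent(scaled, range(p))$exponent, 2,
               tolerance = 1e-10)
  # zero values are excluded from the fit
  withz <- rbind(exact, data.frame(p = 21000, eps_g = 0))
  f3 <- fit_power_exponent(withz, c(1000, 21000))
  expect_equal(f3$n_points, length(p))
  # noisy recovery within 0.2
  set.seed(702)
  noisy <- data.frame(p = p[1:10],
                      eps_g = 5 * p[1:10]^-1.5 *
                        exp(rnorm(10, 0, 0.2)))
  expect_lt(abs(fit_power_exponent(noisy, range(p))$exponent - 1.5), 0.2)
})

test_that("frozen dynamics give a flat learning curve", {
  cfg <- curve_config("synaptic", n_units = 40, max_p = 600,
                      stdp = stdp_params(enabled = FALSE),
                      learning = learning_params(enabled = FALSE),
                      schedule = eval_schedule(eval_every = 200,
                                               n_test = 150, n_repeats = 3),
                      seed = 703)
  cv <- run_learning_curve(cfg)
  expect_equal(nrow(cv$points), 3L)
  spread <- diff(range(cv$points$eps_g))
  # flat within sampling error (a few standard errors of the points)
  expect_lt(spread, 6 * max(cv$points$stderr, 1e-4))
  expect_equal(sum(cv$step_counts), 0)
})

test_that("a teacher-equal student yields an identically zero curve", {
  seeds <- spikelearn:::derive_streams(704L)
  set.seed(seeds[["teacher"]])
  t <- synaptic_perceptron(40)
  pair <- teacher_student_pair(t, t)
  res <- generalization_error(pair, eval_schedule(n_test = 50))
  expect_identical(res$repeats, rep(0, 3))
})

test_that("training trajectories are identical with or without evaluation", {
  base <- curve_config("synaptic", n_units = 40, max_p = 400,
                       schedule = eval_schedule(eval_every = 100,
                                                n_test = 30, n_repeats = 2),
                       seed = 705)
  sparse <- base
  sparse$schedule <- eval_schedule(eval_every = 400, n_test = 30,
                                   n_repeats = 2)
  a <- run_learning_curve(base)
  b <- run_learning_curve(sparse)
  expect_identical(a$pair$student$weights, b$pair$student$weights)
  expect_identical(a$pair$teacher$weights, b$pair$teacher$weights)
  # and the measurement at the shared point agrees exactly
  expect_equal(a$points$eps_g[nrow(a$points)],
               b$points$eps_g[nrow(b$points)])
})

test_that("a small dendritic run synchronizes exactly and stops", {
  cfg <- curve_config("dendritic", n_units = 50, max_p = 20000,
                      stdp = stdp_params(amplitude = 0.003,
                                         mode = "rank_window"),
                      learning = learning_params(step_size = 1 / 50),
                      schedule = eval_schedule(eval_every = 2000,
                                               n_test = 200, n_repeats = 3),
                      seed = 706)
  cv <- run_learning_curve(cfg)
  expect_false(is.na(cv$first_identical_p))
  expect_identical(cv$pair$teacher$strengths, cv$pair$student$strengths)
  # the measurement taken at the identity point is exactly zero
  expect_identical(cv$points$eps_g[nrow(cv$points)], 0)
})
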