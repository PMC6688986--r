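test_that("identical teacher and student never mismatch", {
  set.seed(501)
  t <- synaptic_perceptron(60)
  pair <- teacher_student_pair(t, t)
  for (i in 1:5) {
    res <- present_example(pair, generate_synaptic_example(60))
    expect_equal(res$mismatch, 0)
    expect_equal(nrow(res$steps %||% data.frame()), 0)
    pair <- res$pair
  }
})

test_that("frozen dynamics leave all parameters unchanged", {
  set.seed(502)
  pair <- toy_pair(runif(40, 0.3, 0.7), runif(40, 0.3, 0.7),
                   enabled_adapt = FALSE, enabled_learn = FALSE)
  w0T <- pair$teacher$weights
  w0S <- pair$student$weights
  for (i in 1:10) pair <- present_example(pair,
                            generate_synaptic_example(40))$pair
  expect_identical(pair$teacher$weights, w0T)
  expect_identical(pair$student$weights, w0S)
})

test_that("the N=2 toy follows the hand-simulated protocol", {
  # teacher w1 = 1.3 spikes on unit 1; student w1 = 0.1 stays silent;
  # exactly one conflict and one learning step of +lambda * x
  pair <- toy_pair(c(1.3, 0.1), c(0.1, 0.1), step_size = 0.001,
                   enabled_adapt = FALSE)
  ex <- toy_example(unit = 1L, time = 0, amplitude = 1, n_units = 2L)
  res <- present_example(pair, ex, record_steps = TRUE)
  expect_equal(res$teacher_trace$per_event_output, 1L)
  expect_equal(res$student_trace$per_event_output, 0L)
  expect_equal(res$mismatch, 1)
  expect_equal(nrow(res$steps), 1L)
  expect_equal(res$pair$student$weights[1], 0.101)
  expect_equal(res$pair$teacher$weights, c(1.3, 0.1))
  expect_equal(classify_step(res$steps$teacher_before,
                             res$steps$student_before,
                             res$steps$student_post,
                             res$steps$student_pre), "attractive")
})

test_that("scenario mismatch is rejected", {
  set.seed(503)
  t <- synaptic_perceptron(20)
  pair <- teacher_student_pair(t, t)
  expect_error(present_example(pair, generate_dendritic_example(20)),
               "scenario")
})

test_that("mismatch count equals the number of step records", {
  set.seed(504)
  pair <- toy_pair(runif(60, 0.3, 0.7), runif(60, 0.3, 0.7))
  total_mism <- 0L
  total_steps <- 0L
  for (i in 1:20) {
    res <- present_example(pair, generate_synaptic_example(60),
                           record_steps = TRUE)
    pair <- res$pair
    total_mism <- total_mism + res$mismatch
    total_steps <- total_steps + nrow(res$steps)
  }
  expect_gt(total_mism, 0)
  expect_equal(total_steps, total_mism)
})

test_that("fused protocol equals the composed granular operations", {
  # teacher-following mode, synaptic: lif_run + adapt_synaptic +
  # learning_step applied by hand must reproduce present_example exactly
  set.seed(505)
  N <- 50L
  wT <- runif(N, 0.3, 0.7)
  wS <- runif(N, 0.3, 0.7)
  pair <- toy_pair(wT, wS)
  ex <- generate_synaptic_example(N)
  ev <- ex$events

  trT <- lif_run(ex, wT[ev$unit] * ev$amplitude)
  trS <- lif_run(ex, wS[ev$unit] * ev$amplitude)
  prm <- stdp_params(amplitude = 0.003, kernel = "step")
  wT2 <- adapt_synaptic(wT, ex, trT, params = prm)
  # student repeats the teacher's factors on its own weights
  wS2 <- wS * (wT2 / wT)
  wS2 <- pmin(pmax(wS2, 1e-4), 1.5)
  for (k in seq_len(nrow(ev))) {
    oT <- trT$per_event_output[k]
    oS <- trS$per_event_output[k]
    if (oT != oS) {
      u <- ev$unit[k]
      wS2[u] <- learning_step(wS2[u], oT, oS, ev$amplitude[k],
                              learning_params(step_size = 0.001))
    }
  }
  res <- present_example(pair, ex)
  expect_equal(res$teacher_trace$per_event_output, trT$per_event_output)
  expect_equal(res$student_trace$per_event_output, trS$per_event_output)
  expect_equal(res$pair$teacher$weights, wT2, tolerance = 1e-14)
  expect_equal(res$pair$student$weights, wS2, tolerance = 1e-14)
})

test_that("dendritic fused protocol equals composed granular operations", {
  set.seed(506)
  N <- 50L
  t <- dendritic_perceptron(N)
  s <- dendritic_perceptron(N, fixed_weights = t$fixed_weights)
  prm <- stdp_params(amplitude = 0.003, mode = "rank_window")
  pair <- teacher_student_pair(t, s, stdp = prm,
                               learning = learning_params(step_size = 0.02))
  ex <- generate_dendritic_example(N,
          input_gen_params(weak_fill_amplitude = 0.01))
  ev <- ex$events

  trT <- network_response(t, ex)
  trS <- network_response(s, ex)
  JT2 <- adapt_dendritic(t$strengths, ex, trT, params = prm,
                         bounds = t$bounds)
  JS2 <- pmin(pmax(s$strengths * (JT2 / t$strengths), 0.1), 2)
  for (k in seq_len(nrow(ev))) {
    oT <- trT$per_event_output[k]
    oS <- trS$per_event_output[k]
    if (oT != oS) {
      d <- ev$dendrite[k]
      JS2[d] <- learning_step(JS2[d], oT, oS, ev$amplitude[k],
                              learning_params(step_size = 0.02),
                              bounds = c(0.1, 2))
    }
  }
  res <- present_example(pair, ex)
  expect_equal(res$pair$teacher$strengths, JT2, tolerance = 1e-14)
  expect_equal(res$pair$student$strengths, JS2, tolerance = 1e-14)
})

test_that("architecture stays immutable during a run", {
  set.seed(507)
  t <- dendritic_perceptron(50)
  s <- dendritic_perceptron(50, fixed_weights = t$fixed_weights)
  pair <- teacher_student_pair(t, s,
            stdp = stdp_params(mode = "rank_window"))
  w0 <- pair$teacher$fixed_weights
  for (i in 1:10)
    pair <- present_example(pair,
              generate_dendritic_example(50,
                input_gen_params(weak_fill_amplitude = 0.01)))$pair
  expect_identical(pair$teacher$fixed_weights, w0)
  expect_identical(pair$student$fixed_weights, w0)
  # bounds always respected
  expect_true(all(pair$teacher$strengths >= 0.1 &
                  pair$teacher$strengths <= 2))
  expect_true(all(pair$student$strengths >= 0.1 &
                  pair$student$strengths <= 2))
})
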