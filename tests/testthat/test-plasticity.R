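test_that("stdp_delta evaluates both kernels with sign and cutoff", {
  pexp <- stdp_params(amplitude = 0.003, kernel = "exp")
  expect_equal(stdp_delta(15, pexp), 0.003 * exp(-1), tolerance = 1e-12)
  expect_equal(stdp_delta(-15, pexp), -0.003 * exp(-1), tolerance = 1e-12)
  pstep <- stdp_params(amplitude = 0.003, kernel = "step")
  expect_equal(stdp_delta(-10, pstep), -0.003)
  expect_equal(stdp_delta(10, pstep), 0.003)
  # zero lag and beyond-cutoff lags produce no change
  expect_equal(stdp_delta(0, pexp), 0)
  expect_equal(stdp_delta(60, pexp), 0)
  expect_equal(stdp_delta(c(-60, 60), pstep), c(0, 0))
})

test_that("adapt_synaptic strengthens/weakens only sub-threshold weights", {
  # one spike at t = 0 (unit 1, w = 1.3), one sub-threshold stim at t = 10
  ex <- toy_example(unit = c(1L, 2L), time = c(0, 10), n_units = 2L)
  w <- c(1.3, 0.5)
  tr <- lif_run(ex, w * ex$events$amplitude)
  expect_equal(tr$per_event_output, c(1L, 0L))
  w2 <- adapt_synaptic(w, ex, tr, params = stdp_params(kernel = "step"))
  expect_equal(w2[2], 0.5 * 1.003)        # stimulation after spike
  expect_equal(w2[1], 1.3)                # spiking weight untouched
  # clipping at the upper bound
  w3 <- adapt_synaptic(c(1.3, 1.4999), ex, tr,
                       params = stdp_params(kernel = "step"))
  expect_equal(w3[2], 1.5)
  expect_error(adapt_synaptic(c(2, 0.5), ex, tr), "within")
})

test_that("nearest-spike pairing honors the cutoff and tie-break", {
  # spikes at 0 and 30; stim at 14 is closer to 0 (lag +14); stim at 15 is
  # equidistant -> earlier spike wins (lag +15)
  ex <- toy_example(unit = 1:4, time = c(0, 14, 15, 90), n_units = 8L)
  w <- c(1.3, 0.5, 0.5, 0.5)
  drv <- c(1.3, 0.0, 0.0, 0.5)   # force outputs: spike, sub, sub, sub
  tr <- lif_run(ex, drv)
  expect_equal(tr$per_event_output, c(1L, 0L, 0L, 0L))
  pexp <- stdp_params(kernel = "exp")
  w2 <- adapt_synaptic(w, ex, tr, params = pexp)
  expect_equal(w2[2], 0.5 * (1 + 0.003 * exp(-14 / 15)), tolerance = 1e-12)
  expect_equal(w2[3], 0.5 * (1 + 0.003 * exp(-15 / 15)), tolerance = 1e-12)
  expect_equal(w2[4], 0.5)                # 90 ms: beyond the 50 ms window
})

test_that("adapt_dendritic applies rank-window factors and clips", {
  # two dendrites; d1 spikes at t = 0 (rank 1), d2 sub-threshold at t = 5
  # (rank 2): lag +5 -> strengthen by (1 + A)
  ex <- toy_example(unit = c(1L, 6L), time = c(0, 5), n_units = 10L,
                    dendrite = c(1L, 2L), rank = c(1, 2), n_dendrites = 2L)
  tr <- structure(list(per_event_output = c(1L, 0L), times = ex$events$time,
                       spike_times = 0, subthreshold_events = 2L),
                  class = "output_trace")
  J <- c(1, 1)
  prm <- stdp_params(mode = "rank_window")
  J2 <- adapt_dendritic(J, ex, tr, params = prm)
  expect_equal(J2, c(1, 1.003))
  # spike still inside a tighter rank window of 1
  J3 <- adapt_dendritic(J, ex, tr, params = stdp_params(mode = "rank_window",
                                                        rank_window = 1))
  expect_equal(J3[2], 1.003)
  # clipping at J_max = 2 after two strengthening pairings
  ex2 <- toy_example(unit = c(1L, 2L, 6L), time = c(0, 3, 5), n_units = 10L,
                     dendrite = c(1L, 1L, 2L), rank = c(1, 1, 2),
                     n_dendrites = 2L)
  tr2 <- structure(list(per_event_output = c(1L, 1L, 0L),
                        times = ex2$events$time, spike_times = c(0, 3),
                        subthreshold_events = 3L),
                   class = "output_trace")
  J4 <- adapt_dendritic(c(1, 1.999), ex2, tr2, params = prm)
  expect_equal(J4[2], 2)
  expect_lt(1.999 * 1.003^2, 2.02)   # un-clipped value would exceed 2
})

test_that("same-dendrite spikes never adapt their own strength", {
  ex <- toy_example(unit = c(1L, 2L), time = c(0, 5), n_units = 10L,
                    dendrite = c(1L, 1L), rank = c(1, 1), n_dendrites = 2L)
  tr <- structure(list(per_event_output = c(1L, 0L), times = ex$events$time,
                       spike_times = 0, subthreshold_events = 2L),
                  class = "output_trace")
  J2 <- adapt_dendritic(c(1, 1), ex, tr, params = stdp_params(mode = "rank_window"))
  expect_equal(J2, c(1, 1))
})

test_that("teacher-following adaptation preserves the weight ratio until a clip", {
  set.seed(301)
  N <- 60L
  pair <- toy_pair(runif(N, 0.3, 0.7), runif(N, 0.3, 0.7),
                   enabled_learn = FALSE)
  ratio0 <- pair$student$weights / pair$teacher$weights
  clipped <- FALSE
  for (i in 1:30) {
    ex <- generate_synaptic_example(N)
    res <- present_example(pair, ex)
    pair <- res$pair
    atb <- pair$teacher$weights %in% pair$teacher$bounds |
           pair$student$weights %in% pair$student$bounds
    ratio <- pair$student$weights / pair$teacher$weights
    expect_equal(ratio[!atb], ratio0[!atb], tolerance = 1e-12)
    clipped <- clipped || any(atb)
    # a clip never widens the absolute gap
    if (any(atb)) ratio0[atb] <- ratio[atb]
  }
})

test_that("exact teacher-student equality is absorbing", {
  set.seed(302)
  N <- 40L
  w <- runif(N, 0.2, 0.8)
  pair <- toy_pair(w, w)
  for (i in 1:20) {
    ex <- generate_synaptic_example(N)
    res <- present_example(pair, ex)
    pair <- res$pair
    expect_equal(res$mismatch, 0)
    expect_identical(pair$teacher$weights, pair$student$weights)
  }
})

test_that("step and exponential kernels give matching qualitative trends", {
  run_short <- function(kernel) {
    set.seed(303)
    pair <- toy_pair(runif(60, 0.3, 0.7), runif(60, 0.3, 0.7),
                     step_size = 0.01)
    pair$stdp <- stdp_params(amplitude = 0.003, kernel = kernel)
    m0 <- 0; m1 <- 0
    for (i in 1:600) {
      ex <- generate_synaptic_example(60)
      res <- present_example(pair, ex)
      pair <- res$pair
      if (i <= 150) m0 <- m0 + res$mismatch else if (i > 450)
        m1 <- m1 + res$mismatch
    }
    c(early = m0 / 150, late = m1 / 150)
  }
  s <- run_short("step")
  e <- run_short("exp")
  # both kernels reduce the mismatch rate over training
  expect_lt(s[["late"]], s[["early"]])
  expect_lt(e[["late"]], e[["early"]])
})
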