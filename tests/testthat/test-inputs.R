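test_that("synaptic examples stimulate exactly N/2 distinct units", {
  set.seed(101)
  for (N in c(2L, 10L, 100L, 1000L)) {
    ex <- generate_synaptic_example(N)
    expect_equal(nrow(ex$events), N / 2)
    expect_equal(anyDuplicated(ex$events$unit), 0L)
    expect_false(is.unsorted(ex$events$time))
    expect_true(all(ex$events$amplitude >= 0.8 &
                    ex$events$amplitude <= 1.2))
    expect_silent(validate_async_example(ex))
  }
  expect_error(generate_synaptic_example(101), "even")
  expect_error(generate_synaptic_example(0), "even")
})

test_that("single-event example has no defined mean gap", {
  set.seed(102)
  ex <- generate_synaptic_example(2)
  expect_equal(nrow(ex$events), 1L)
  expect_true(is.na(mean_consecutive_gap(ex)))
})

test_that("event times sit on the resolution grid", {
  set.seed(103)
  ex <- generate_synaptic_example(100)
  expect_equal(ex$events$time, round(ex$events$time / 0.01) * 0.01)
  ml <- generate_multilayer_example(100)
  expect_equal(ml$events$time, round(ml$events$time / 1e-4) * 1e-4,
               tolerance = 1e-12)
})

test_that("mean consecutive gap is calibrated to 5 ms", {
  # oracle: n points uniform on [0, L] have expected consecutive spacing
  # L / (n + 1); the generator uses L = 5 * (n + 1), so the expected gap is
  # exactly 5 ms.  Checked against the closed form at reduced sample size.
  set.seed(104)
  gaps <- replicate(1500, mean_consecutive_gap(generate_synaptic_example(100)))
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 5), 3 * se)
})

test_that("amplitudes average 1 over many events", {
  set.seed(105)
  amps <- unlist(replicate(200, generate_synaptic_example(100)$events$amplitude,
                           simplify = FALSE))
  se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - 1), 3 * se)
})

test_that("generation is reproducible under a fixed seed", {
  set.seed(106); a <- generate_synaptic_example(100)
  set.seed(106); b <- generate_synaptic_example(100)
  expect_identical(a, b)
  set.seed(106); d1 <- generate_dendritic_example(100)
  set.seed(106); d2 <- generate_dendritic_example(100)
  expect_identical(d1, d2)
  set.seed(106); m1 <- generate_multilayer_example(100)
  set.seed(106); m2 <- generate_multilayer_example(100)
  expect_identical(m1, m2)
})

test_that("dendritic examples stimulate K/2 contiguous ordered blocks", {
  set.seed(107)
  ex <- generate_dendritic_example(1000)
  expect_equal(ex$n_dendrites, 200L)
  expect_equal(length(unique(ex$events$dendrite)), 100L)
  expect_equal(nrow(ex$events), 500L)
  expect_silent(validate_async_example(ex))
  # block-ordering invariant: block i ends before block j > i starts
  spans <- t(vapply(split(ex$events$time, ex$events$rank), range,
                    numeric(2)))
  expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
  # smallest valid instance: N = 10, one chosen dendrite of two
  set.seed(108)
  sm <- generate_dendritic_example(10)
  expect_equal(nrow(sm$events), 5L)
  expect_equal(length(unique(sm$events$dendrite)), 1L)
  expect_error(generate_dendritic_example(12), "divisible by 10")
})

test_that("weak fill stimulates every unit of the unchosen dendrites", {
  set.seed(109)
  ex <- generate_dendritic_example(1000,
          input_gen_params(weak_fill_amplitude = 0.01))
  expect_equal(nrow(ex$events), 1000L)
  weak <- ex$events[ex$events$weak, ]
  expect_equal(nrow(weak), 500L)
  expect_true(all(weak$amplitude == 0.01))
  # weak events cover exactly the units of unchosen dendrites
  expect_equal(anyDuplicated(ex$events$unit), 0L)
  expect_setequal(ex$events$unit, 1:1000)
})

test_that("multilayer examples have unit amplitudes at fine resolution", {
  set.seed(110)
  ex <- generate_multilayer_example(100)
  expect_equal(nrow(ex$events), 50L)
  expect_true(all(ex$events$amplitude == 1))
})

test_that("examples round-trip exactly through TSV and JSON", {
  set.seed(111)
  for (ex in list(generate_synaptic_example(20),
                  generate_dendritic_example(20))) {
    tsv <- tempfile(fileext = ".tsv")
    example_to_tsv(ex, tsv)
    back <- example_from_tsv(tsv)
    expect_identical(back$events, ex$events)
    expect_identical(back$n_units, ex$n_units)
    js <- tempfile(fileext = ".json")
    example_to_json(ex, js)
    backj <- example_from_json(js)
    expect_identical(backj$events[, names(ex$events)], ex$events)
    unlink(c(tsv, js))
  }
})
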