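# Small hand-built fixtures used across test files.

# an example with explicit events (synaptic unless dendrite/rank given)
toy_example <- function(unit, time, amplitude = rep(1, length(unit)),
                        n_units = max(unit), dendrite = NULL, rank = NULL,
                        n_dendrites = NULL) {
  ev <- data.frame(unit = as.integer(unit), time = time,
                   amplitude = amplitude)
  scenario <- "synaptic"
  if (!is.null(dendrite)) {
    ev$dendrite <- as.integer(dendrite)
    ev$rank <- rank
    scenario <- "dendritic"
  }
  structure(list(events = ev, n_units = as.integer(n_units),
                 scenario = scenario, n_dendrites = n_dendrites),
            class = "async_example")
}

# a pure-R fixed-step integrator, deliberately naive: used to cross-check
# the compiled oracle on short traces
r_fixed_step_lif <- function(times, drives, dt = 0.001, tau = 20, vth = 1) {
  steps <- round(times / dt)
  v <- 0
  out <- integer(length(times))
  f <- exp(-dt / tau)
  cur <- 0
  for (k in seq_along(times)) {
    v <- v * f^(steps[k] - cur)
    cur <- steps[k]
    v <- v + drives[k]
    if (v >= vth) { out[k] <- 1L; v <- 0 } else out[k] <- 0L
  }
  out
}

# deterministic synaptic pair with chosen weights
toy_pair <- function(wT, wS, step_size = 0.001, A = 0.003,
                     bounds = c(1e-4, 1.5), source = "teacher",
                     enabled_adapt = TRUE, enabled_learn = TRUE) {
  n <- length(wT)
  t <- synaptic_perceptron(n, weights = wT, bounds = bounds)
  s <- synaptic_perceptron(n, weights = wS, bounds = bounds)
  teacher_student_pair(
    t, s,
    stdp = stdp_params(amplitude = A, enabled = enabled_adapt),
    learning = learning_params(step_size = step_size,
                               enabled = enabled_learn),
    adaptation_source = source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
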