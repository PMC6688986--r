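#' Leaky integrate-and-fire parameters
#'
#' The model is used in scaled form: resting potential 0, spiking threshold
#' 1.  Between delta-function inputs the voltage decays exponentially toward
#' rest with time constant `tau_mem`; an input raises the voltage instantly
#' by its effective drive; reaching the threshold (`V >= v_threshold`) emits
#' a spike and resets the voltage to rest.
#'
#' @param tau_mem membrane time constant in ms (default 20).
#' @param v_threshold scaled spiking threshold (default 1).
#' @param v_rest scaled resting potential (default 0).
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(tau_mem = 20, v_threshold = 1, v_rest = 0) {
  check_scalar_number(tau_mem, "tau_mem")
  if (tau_mem <= 0) stopf("`tau_mem` must be > 0")
  if (v_threshold <= v_rest) stopf("`v_threshold` must exceed `v_rest`")
  structure(list(tau_mem = tau_mem, v_threshold = v_threshold,
                 v_rest = v_rest),
            class = "lif_params")
}

#' Closed-form voltage decay between events
#'
#' Returns `v_rest + (v - v_rest) * exp(-dt / tau_mem)`, the exact solution
#' of the membrane equation in the absence of input.
#'
#' @param v scaled voltage at the start of the interval.
#' @param dt elapsed time in ms (non-negative).
#' @param params a [lif_params()] object.
#' @return the decayed voltage.
#' @export
lif_decay <- function(v, dt, params = lif_params()) {
  if (any(dt < 0)) stopf("`dt` must be non-negative")
  params$v_rest + (v - params$v_rest) * exp(-dt / params$tau_mem)
}

#' A fresh neuron state
#'
#' @param n_dendrites for the dendritic scenario, one independent voltage per
#'   dendrite; default 1 (a single compartment).
#' @return an object of class `neuron_state` with fields `voltage`,
#'   `last_event_time` and `spike_times`.
#' @export
neuron_state <- function(n_dendrites = 1L) {
  structure(list(voltage = rep(0, n_dendrites),
                 last_event_time = rep(0, n_dendrites),
                 spike_times = numeric(0)),
            class = "neuron_state")
}

#' Apply one stimulation event to a neuron state
#'
#' Decays the (compartment) voltage to `time`, adds `drive`, and tests the
#' threshold: at or above it the output bit is 1, the spike time is recorded
#' and the voltage resets to rest; otherwise the output bit is 0.
#'
#' @param state a [neuron_state()].
#' @param time event time in ms; must not precede the compartment's last
#'   event.
#' @param drive effective input amplitude (`w * x`, or `J * w * x`);
#'   non-negative.
#' @param params a [lif_params()] object.
#' @param compartment which voltage to update (dendritic scenario); default 1.
#' @return a list with the updated `state` and the `output` bit.
#' @export
lif_apply_event <- function(state, time, drive, params = lif_params(),
                            compartment = 1L) {
  if (time < state$last_event_time[compartment])
    stopf("event time regresses below the last event time")
  if (drive < 0) stopf("`drive` must be non-negative")
  v <- lif_decay(state$voltage[compartment],
                 time - state$last_event_time[compartment], params)
  v <- v + drive
  out <- 0L
  if (v >= params$v_threshold) {
    out <- 1L
    state$spike_times <- c(state$spike_times, time)
    v <- params$v_rest
  }
  state$voltage[compartment] <- v
  state$last_event_time[compartment] <- time
  list(state = state, output = out)
}

new_output_trace <- function(output, times, dendrite = NULL,
                             v_peak = NULL) {
  structure(list(per_event_output = as.integer(output),
                 times = times,
                 spike_times = times[output == 1L],
                 subthreshold_events = which(output == 0L),
                 dendrite = dendrite,
                 v_peak = v_peak),
            class = "output_trace")
}

#' @export
print.output_trace <- function(x, ...) {
  cat(sprintf("<output_trace: %d events, %d spikes>\n",
              length(x$per_event_output), length(x$spike_times)))
  invisible(x)
}

#' Run one example through a LIF output stage
#'
#' Event-driven simulation with one effective drive per stimulation event.
#' For dendritic examples each dendrite carries an independent voltage that
#' integrates only its own members' events; a spike resets only the dendrite
#' that fired.  The initial voltage is the resting potential.
#'
#' @param example an `async_example`.
#' @param drives numeric vector of effective drives, one per event, in the
#'   example's event order.
#' @param params a [lif_params()] object.
#' @return an `output_trace`: `per_event_output` (0/1 per event),
#'   `spike_times`, `subthreshold_events`, and the per-event peak voltage
#'   `v_peak` (just after the drive is added, before any reset).
#' @export
lif_run <- function(example, drives, params = lif_params()) {
  ev <- example$events
  if (length(drives) != nrow(ev))
    stopf("need exactly one drive per event (%d != %d)",
          length(drives), nrow(ev))
  if (params$v_rest != 0)
    stopf("the event-driven core assumes the scaled model (v_rest = 0)")
  if (example$scenario == "dendritic") {
    dd <- as.integer(ev$dendrite) - 1L
    res <- lif_run_dendritic_cpp(ev$time, as.numeric(drives), dd,
                                 example$n_dendrites,
                                 params$tau_mem, params$v_threshold)
    new_output_trace(res$output, ev$time, dendrite = ev$dendrite,
                     v_peak = res$v_peak)
  } else {
    res <- lif_run_cpp(ev$time, as.numeric(drives),
                       params$tau_mem, params$v_threshold)
    new_output_trace(res$output, ev$time, v_peak = res$v_peak)
  }
}

#' Brute-force fixed-step LIF integration (validation oracle)
#'
#' Integrates the membrane equation on a regular time grid of width `dt`
#' (4th-order decay per step), injecting each drive at its nearest grid
#' point.  Independent of the event-driven path; used to validate it.
#'
#' @inheritParams lif_run
#' @param dt integration step in ms (default 0.001).
#' @return an `output_trace` (single-compartment examples only).
#' @export
lif_run_fixed_step <- function(example, drives, params = lif_params(),
                               dt = 0.001) {
  ev <- example$events
  if (length(drives) != nrow(ev))
    stopf("need exactly one drive per event")
  res <- lif_fixed_step_cpp(ev$time, as.numeric(drives), dt,
                            params$tau_mem, params$v_threshold)
  new_output_trace(res$output, ev$time, v_peak = res$v_peak)
}
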