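#' Parameters of the asynchronous input generator
#'
#' An example (one "input") stimulates half of the input units, each once, at
#' random times on a discrete grid.  Delays are uniform with a mean
#' consecutive time-lag of `mean_gap_ms`; amplitudes are uniform on
#' `amplitude_range`.
#'
#' @param resolution_ms time grid of the delays, in ms.  The default 0.01 is
#'   used for the single-layer scenarios; the two-layer scenario uses 0.001
#'   (0.0001 for N = 100).
#' @param mean_gap_ms target mean time-lag between consecutive stimulations
#'   (ms); default 5.
#' @param amplitude_range range of the uniform stimulation amplitudes.
#' @param weak_fill_amplitude if non-`NULL` (dendritic scenario only), every
#'   unit of the non-stimulated dendrites receives one extra stimulation at
#'   this amplitude (e.g. 0.01) at a random time within the example span, so
#'   that no dendritic strength can freeze.
#' @return an object of class `input_gen_params`.
#' @export
input_gen_params <- function(resolution_ms = 0.01, mean_gap_ms = 5,
                             amplitude_range = c(0.8, 1.2),
                             weak_fill_amplitude = NULL) {
  check_scalar_number(resolution_ms, "resolution_ms")
  check_scalar_number(mean_gap_ms, "mean_gap_ms")
  if (resolution_ms <= 0) stopf("`resolution_ms` must be > 0")
  if (mean_gap_ms <= 0) stopf("`mean_gap_ms` must be > 0")
  if (length(amplitude_range) != 2L || amplitude_range[1] <= 0 ||
      diff(amplitude_range) < 0)
    stopf("`amplitude_range` must be an increasing pair with lower bound > 0")
  if (!is.null(weak_fill_amplitude)) {
    check_scalar_number(weak_fill_amplitude, "weak_fill_amplitude")
    if (weak_fill_amplitude <= 0) stopf("`weak_fill_amplitude` must be > 0")
  }
  structure(list(resolution_ms = resolution_ms, mean_gap_ms = mean_gap_ms,
                 amplitude_range = amplitude_range,
                 weak_fill_amplitude = weak_fill_amplitude),
            class = "input_gen_params")
}

snap_to_grid <- function(t, res) round(t / res) * res

new_async_example <- function(events, n_units, scenario,
                              n_dendrites = NULL, dendrite_order = NULL) {
  structure(list(events = events, n_units = as.integer(n_units),
                 scenario = scenario, n_dendrites = n_dendrites,
                 dendrite_order = dendrite_order),
            class = "async_example")
}

#' @export
print.async_example <- function(x, ...) {
  cat(sprintf("<async_example: %s, N = %d, %d events, span %.2f ms>\n",
              x$scenario, x$n_units, nrow(x$events),
              if (nrow(x$events)) max(x$events$time) else 0))
  invisible(x)
}

#' Generate one asynchronous example for the synaptic scenario
#'
#' Stimulates `n_units / 2` distinct input units, each once.  The delays are
#' drawn uniformly on a window of length `mean_gap_ms * (n_events + 1)` and
#' snapped to the resolution grid, so that the expected time-lag between
#' consecutive stimulations equals `mean_gap_ms` exactly; amplitudes are
#' uniform on the configured range.  Events are sorted by time, ties broken
#' by unit index.  Randomness comes from R's global RNG: call [set.seed()]
#' for reproducibility.
#'
#' @param n_units number of input units N (positive even integer).
#' @param params an [input_gen_params()] object.
#' @return an `async_example` whose `events` data frame has columns `unit`
#'   (1-based), `time` (ms) and `amplitude`.
#' @export
generate_synaptic_example <- function(n_units, params = input_gen_params()) {
  n_units <- as.integer(n_units)
  if (n_units <= 0L || n_units %% 2L != 0L)
    stopf("`n_units` must be a positive even integer")
  n <- n_units %/% 2L
  ev <- draw_uniform_events(n, n_units, params,
                            amp = runif(n, params$amplitude_range[1],
                                        params$amplitude_range[2]))
  new_async_example(ev, n_units, "synaptic")
}

#' Generate one asynchronous example for the two-layer scenario
#'
#' As [generate_synaptic_example()], but all stimulation amplitudes are 1 and
#' the delay grid defaults to the fine two-layer resolution (0.001 ms, or
#' 0.0001 ms when `n_units <= 100`).
#'
#' @inheritParams generate_synaptic_example
#' @param params an [input_gen_params()] object, or `NULL` for the scenario
#'   default.
#' @export
generate_multilayer_example <- function(n_units, params = NULL) {
  n_units <- as.integer(n_units)
  if (n_units <= 0L || n_units %% 2L != 0L)
    stopf("`n_units` must be a positive even integer")
  if (is.null(params)) {
    params <- input_gen_params(
      resolution_ms = if (n_units <= 100L) 1e-4 else 1e-3)
  }
  n <- n_units %/% 2L
  ev <- draw_uniform_events(n, n_units, params, amp = rep(1, n))
  new_async_example(ev, n_units, "multilayer")
}

draw_uniform_events <- function(n, n_units, params, amp) {
  units <- sample.int(n_units, n)
  times <- snap_to_grid(runif(n, 0, params$mean_gap_ms * (n + 1)),
                        params$resolution_ms)
  o <- order(times, units)
  data.frame(unit = units[o], time = times[o], amplitude = amp[o])
}

#' Generate one asynchronous example for the dendritic scenario
#'
#' The N input units are wired in groups of five to K = N/5 dendrites.  Half
#' of the dendrites are chosen at random; the five units of each chosen
#' dendrite are stimulated sequentially in random member order, with i.i.d.
#' consecutive gaps uniform on (0, 2 * `mean_gap_ms`] snapped to the grid
#' (floored at one grid step), so blocks of the same dendrite are contiguous
#' in time and block order follows dendrite index.  If
#' `params$weak_fill_amplitude` is set, every unit of the unchosen dendrites
#' additionally receives one weak stimulation at a random time within the
#' span of the primary events.
#'
#' @param n_units number of input units N (positive, divisible by 10).
#' @param params an [input_gen_params()] object.
#' @return an `async_example` with extra event columns `dendrite` (1-based),
#'   `rank` (stimulation rank of the event's dendrite; a weak-fill event
#'   sits between blocks at rank k + 0.5) and `weak`, plus fields
#'   `n_dendrites` and `dendrite_order` (rank by chosen dendrite).
#' @export
generate_dendritic_example <- function(n_units, params = input_gen_params()) {
  n_units <- as.integer(n_units)
  if (n_units <= 0L || n_units %% 10L != 0L)
    stopf("`n_units` must be a positive integer divisible by 10")
  K <- n_units %/% 5L
  n_blocks <- K %/% 2L
  chosen <- sort(sample.int(K, n_blocks))
  # member order random within a dendrite; block order follows dendrite index
  units <- unlist(lapply(chosen, function(d) {
    members <- (d - 1L) * 5L + 1:5
    if (length(members) > 1L) sample(members) else members
  }), use.names = FALSE)
  n <- length(units)
  res <- params$resolution_ms
  gaps <- pmax(res, snap_to_grid(runif(n, 0, 2 * params$mean_gap_ms), res))
  times <- cumsum(gaps)
  ev <- data.frame(unit = units, time = times,
                   amplitude = runif(n, params$amplitude_range[1],
                                     params$amplitude_range[2]),
                   dendrite = rep(chosen, each = 5L),
                   rank = rep(seq_len(n_blocks), each = 5L),
                   weak = FALSE)
  if (!is.null(params$weak_fill_amplitude)) {
    unchosen <- setdiff(seq_len(K), chosen)
    wunits <- as.integer(outer(1:5, (unchosen - 1L) * 5L, `+`))
    span <- max(times)
    wt <- snap_to_grid(runif(length(wunits), 0, span), res)
    # a weak event sits "between" blocks at rank k + 0.5 (k blocks already
    # started), so its +-2 rank window covers exactly the two prior-ranked
    # and the two later-ranked stimulated dendrites
    block_start <- times[seq(1L, n, by = 5L)]
    wrank <- findInterval(wt, block_start) + 0.5
    wev <- data.frame(unit = wunits, time = wt,
                      amplitude = params$weak_fill_amplitude,
                      dendrite = rep(unchosen, each = 5L),
                      rank = wrank, weak = TRUE)
    ev <- rbind(ev, wev)
    ev <- ev[order(ev$time, ev$unit), , drop = FALSE]
    rownames(ev) <- NULL
  }
  new_async_example(ev, n_units, "dendritic", n_dendrites = K,
                    dendrite_order = setNames(seq_len(n_blocks), chosen))
}

#' Mean time-lag between consecutive stimulations of an example
#'
#' Computed over the primary (non-weak-fill) events.  Returns `NA` when the
#' example has fewer than two primary events.
#'
#' @param example an `async_example`.
#' @return mean consecutive gap in ms, or `NA_real_`.
#' @export
mean_consecutive_gap <- function(example) {
  ev <- primary_events(example)
  if (nrow(ev) < 2L) return(NA_real_)
  mean(diff(sort(ev$time)))
}

primary_events <- function(example) {
  ev <- example$events
  if (!is.null(ev$weak)) ev <- ev[!ev$weak, , drop = FALSE]
  ev
}

#' Validate the structural invariants of an asynchronous example
#'
#' Checks event ordering, uniqueness of stimulated units, amplitude and time
#' grids, and -- for dendritic examples -- the contiguity and index-ordering
#' of dendrite blocks.  Errors on the first violation.
#'
#' @param example an `async_example`.
#' @param params the generator parameters the example was drawn with.
#' @return `example`, invisibly.
#' @export
validate_async_example <- function(example, params = input_gen_params()) {
  ev <- example$events
  if (is.unsorted(ev$time)) stopf("events not sorted by time")
  if (any(ev$amplitude <= 0)) stopf("non-positive amplitude")
  if (any(ev$time < 0)) stopf("negative event time")
  offgrid <- abs(ev$time / params$resolution_ms -
                 round(ev$time / params$resolution_ms)) > 1e-6
  if (any(offgrid)) stopf("event times off the resolution grid")
  if (anyDuplicated(ev$unit)) stopf("a unit is stimulated more than once")
  if (example$scenario == "dendritic") {
    pr <- ev[if (is.null(ev$weak)) TRUE else !ev$weak, , drop = FALSE]
    spans <- do.call(rbind, lapply(split(pr$time, pr$rank), range))
    if (nrow(spans) > 1L &&
        any(spans[-1L, 1] <= spans[-nrow(spans), 2]))
      stopf("dendrite blocks overlap or are out of order")
    dd <- pr$dendrite[!duplicated(pr$rank)]
    if (is.unsorted(dd)) stopf("block order does not follow dendrite index")
  }
  invisible(example)
}
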