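#' STDP-like adaptation parameters
#'
#' Adaptation acts multiplicatively on sub-threshold-stimulated parameters:
#' `param <- param * (1 + delta(lag))` with `lag = t_stimulation - t_spike`.
#' A stimulation arriving *after* a reference spike (positive lag) is
#' strengthened, one arriving before it is weakened.  Two kernels are
#' supported: the step kernel `delta = +- amplitude` and the exponential
#' kernel `amplitude * exp(-|lag| / tau_stdp) * sign(lag)`; both vanish at
#' zero lag and (in time-window mode) beyond the cutoff window.
#'
#' @param amplitude adaptation amplitude A (dimensionless, e.g. 0.003).
#' @param kernel `"step"` or `"exp"`.
#' @param tau_stdp decay constant of the exponential kernel, ms (default 15).
#' @param cutoff_ms time window beyond which no pairing occurs (default 50).
#' @param mode `"time_window"` (pair with spikes by temporal proximity) or
#'   `"rank_window"` (dendritic variant: pair with spikes of dendrites whose
#'   stimulation rank is within `rank_window` of the stimulated dendrite's
#'   rank, with no time cutoff).
#' @param rank_window half-width of the rank window (default 2: the two
#'   prior and the two later stimulated dendrites).
#' @param pair `"nearest"` (each sub-threshold event pairs with the single
#'   nearest reference spike, ties toward the earlier one) or `"all"` (one
#'   factor per reference spike within the window).  Rank-window mode always
#'   uses all spikes in the window.
#' @param enabled if `FALSE`, adaptation is skipped entirely (frozen
#'   dynamics).
#' @return an object of class `stdp_params`.
#' @export
stdp_params <- function(amplitude = 0.003, kernel = c("step", "exp"),
                        tau_stdp = 15, cutoff_ms = 50,
                        mode = c("time_window", "rank_window"),
                        rank_window = 2, pair = c("nearest", "all"),
                        enabled = TRUE) {
  kernel <- match.arg(kernel)
  mode <- match.arg(mode)
  pair <- match.arg(pair)
  check_scalar_number(amplitude, "amplitude")
  if (amplitude <= 0) stopf("`amplitude` must be > 0")
  if (tau_stdp <= 0) stopf("`tau_stdp` must be > 0")
  if (cutoff_ms <= 0) stopf("`cutoff_ms` must be > 0")
  if (rank_window < 1) stopf("`rank_window` must be >= 1")
  structure(list(amplitude = amplitude, kernel = kernel,
                 tau_stdp = tau_stdp, cutoff_ms = cutoff_ms,
                 mode = mode, rank_window = rank_window, pair = pair,
                 enabled = isTRUE(enabled)),
            class = "stdp_params")
}

#' Signed fractional STDP change for a given lag
#'
#' @param lag signed time-lag `t_stimulation - t_spike` in ms; positive means
#'   the stimulation followed the spike (strengthening).  Vectorized.
#' @param params an [stdp_params()] object.
#' @return the signed fractional change `delta(lag)`; zero at zero lag and
#'   beyond the cutoff window.
#' @export
stdp_delta <- function(lag, params = stdp_params()) {
  d <- if (params$kernel == "exp") {
    params$amplitude * exp(-abs(lag) / params$tau_stdp) * sign(lag)
  } else {
    params$amplitude * sign(lag)
  }
  d[abs(lag) > params$cutoff_ms] <- 0
  d
}

# nearest reference spike for each time in `t` (ties -> earlier spike);
# returns the signed lag, or NA where no spike is within the cutoff
nearest_spike_lag <- function(t, spikes, cutoff) {
  if (length(spikes) == 0L) return(rep(NA_real_, length(t)))
  spikes <- sort(spikes)
  idx <- findInterval(t, spikes)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(spikes))
  dlo <- abs(t - spikes[lo])
  dhi <- abs(spikes[hi] - t)
  pick_lo <- idx >= 1L & (idx >= length(spikes) | dlo <= dhi)
  best <- ifelse(pick_lo, spikes[lo], spikes[hi])
  lag <- t - best
  lag[abs(lag) > cutoff] <- NA_real_
  lag
}

#' Adapt synaptic weights after one example
#'
#' Applies the multiplicative STDP rule to the weights of sub-threshold
#' stimulations in `trace` (events that evoked a spike are exempt).  Each
#' sub-threshold event pairs with reference spikes from `source` according to
#' `params$pair`; the updated weights are clipped into `bounds`.  This is the
#' composable single-network operation; [present_example()] fuses it with
#' output production and learning.
#'
#' @param weights numeric weight vector of length N (within `bounds`).
#' @param example the `async_example` that was presented.
#' @param trace the `output_trace` giving each event's sub-threshold /
#'   spiking classification (the reference network's trace when adapting a
#'   student in teacher-following mode).
#' @param source reference spike train driving the pairing: either an
#'   `output_trace` or a numeric vector of spike times.  Defaults to
#'   `trace`'s own spikes (self-adaptation).
#' @param params an [stdp_params()] object (time-window mode).
#' @param bounds length-2 vector of reflecting weight bounds.
#' @return the adapted, clipped weight vector.
#' @export
adapt_synaptic <- function(weights, example, trace, source = trace,
                           params = stdp_params(),
                           bounds = c(1e-4, 1.5)) {
  if (any(weights < bounds[1] - 1e-12) || any(weights > bounds[2] + 1e-12))
    stopf("`weights` must start within `bounds`")
  spikes <- if (inherits(source, "output_trace")) source$spike_times
            else as.numeric(source)
  ev <- example$events
  sub <- which(trace$per_event_output == 0L)
  for (k in sub) {
    f <- pairing_factor(ev$time[k], spikes, params)
    u <- ev$unit[k]
    weights[u] <- clip_bounds(weights[u] * f, bounds)
  }
  weights
}

pairing_factor <- function(t, spikes, params) {
  if (length(spikes) == 0L) return(1)
  if (params$pair == "all") {
    prod(1 + stdp_delta(t - spikes, params))
  } else {
    lag <- nearest_spike_lag(t, spikes, params$cutoff_ms)
    if (is.na(lag)) 1 else 1 + stdp_delta(lag, params)
  }
}

#' Adapt dendritic strengths after one example
#'
#' For every sub-threshold stimulation of dendrite i, reference spikes from
#' *other* dendrites adapt `J[i]` multiplicatively.  In rank-window mode
#' (the default for this scenario) the reference spikes are those of
#' dendrites whose stimulation rank lies within `params$rank_window` of the
#' stimulated dendrite's rank, each contributing one factor `1 +- A` (or
#' the exponential kernel) whose sign follows the rank order -- a spike
#' from a prior-ranked dendrite strengthens -- with no time cutoff.  Factors
#' accumulate over the whole example; `J` is clipped into `bounds` once at
#' the end, which is what lets teacher and student strengths synchronize at
#' the reflecting boundaries.
#'
#' @param strengths numeric vector of K dendritic strengths.
#' @param example a dendritic `async_example` (with `dendrite`/`rank` event
#'   columns).
#' @param trace the `output_trace` classifying each event (per-dendrite
#'   voltages; the reference network's trace in teacher-following mode).
#' @param source reference trace whose spikes drive the pairing; defaults to
#'   `trace`.  Must be an `output_trace` over the same example.
#' @param params an [stdp_params()] object, normally with
#'   `mode = "rank_window"`.
#' @param bounds length-2 vector of reflecting bounds on J.
#' @return the adapted, clipped strength vector.
#' @export
adapt_dendritic <- function(strengths, example, trace, source = trace,
                            params = stdp_params(mode = "rank_window"),
                            bounds = c(0.1, 2)) {
  if (any(strengths < bounds[1] - 1e-12) ||
      any(strengths > bounds[2] + 1e-12))
    stopf("`strengths` must start within `bounds`")
  ev <- example$events
  o_ref <- source$per_event_output
  spk <- which(o_ref == 1L)
  fac <- rep(1, length(strengths))
  sub <- which(trace$per_event_output == 0L)
  for (k in sub) {
    d <- ev$dendrite[k]
    if (params$mode == "rank_window") {
      sel <- spk[ev$dendrite[spk] != d &
                 abs(ev$rank[spk] - ev$rank[k]) <= params$rank_window]
      if (length(sel)) {
        # rank mode replaces the time cutoff and takes the sign from the
        # stimulation-rank order (spike of a prior-ranked dendrite ->
        # strengthen), so the steps on both sides stay symmetric in number
        # and strength; the exponential kernel keeps its time-lag magnitude
        sgn <- sign(ev$rank[k] - ev$rank[sel])
        mag <- if (params$kernel == "exp") {
          params$amplitude *
            exp(-abs(ev$time[k] - ev$time[sel]) / params$tau_stdp)
        } else {
          params$amplitude
        }
        fac[d] <- fac[d] * prod(1 + sgn * mag)
      }
    } else {
      others <- ev$time[spk[ev$dendrite[spk] != d]]
      fac[d] <- fac[d] * pairing_factor(ev$time[k], others, params)
    }
  }
  clip_bounds(strengths * fac, bounds)
}
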