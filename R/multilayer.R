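#' Construct a one-hidden-layer network
#'
#' An input layer of N units fully connected to a hidden layer of N LIF
#' units, which feed a single LIF output unit.  Transmission delays on both
#' layers are fixed architecture, drawn uniformly on `[0, 5 N / 2]` ms on the
#' scenario's fine resolution grid and redrawn until no two stimulations can
#' arrive simultaneously at any unit (non-degenerate routes): every
#' input-to-output route `(m, h)` is then identifiable by its arrival times.
#'
#' @param n_units N, the number of input units and of hidden units.
#' @param weights1 optional N x N matrix of first-layer weights
#'   (`weights1[m, h]` connects input m to hidden h); default uniform on
#'   `init_range`.
#' @param weights2 optional length-N vector of second-layer weights; default
#'   uniform on `init_range`.
#' @param delays1,delays2 optional fixed delays (same shapes as the weights);
#'   drawn when `NULL`.
#' @param bounds reflecting weight bounds, both layers (default
#'   `c(1e-4, 1.5)`).
#' @param lif a [lif_params()] object.
#' @param init_range initialization range (default `c(0.1, 0.9)`).
#' @param resolution_ms delay grid; default 0.001 ms (0.0001 for N <= 100).
#' @return an object of class `two_layer_network`.
#' @export
two_layer_network <- function(n_units, weights1 = NULL, weights2 = NULL,
                              delays1 = NULL, delays2 = NULL,
                              bounds = c(1e-4, 1.5), lif = lif_params(),
                              init_range = c(0.1, 0.9),
                              resolution_ms = NULL) {
  n_units <- as.integer(n_units)
  if (n_units < 2L || n_units %% 2L != 0L)
    stopf("`n_units` must be a positive even integer")
  if (is.null(resolution_ms))
    resolution_ms <- if (n_units <= 100L) 1e-4 else 1e-3
  if (is.null(weights1))
    weights1 <- matrix(runif(n_units^2, init_range[1], init_range[2]),
                       n_units, n_units)
  if (is.null(weights2))
    weights2 <- runif(n_units, init_range[1], init_range[2])
  if (is.null(delays1) || is.null(delays2)) {
    span <- 5 * n_units / 2
    for (try in 1:100) {
      d1 <- matrix(snap_to_grid(runif(n_units^2, 0, span), resolution_ms),
                   n_units, n_units)
      d2 <- snap_to_grid(runif(n_units, 0, span), resolution_ms)
      # degenerate iff two delays into the same hidden unit coincide, or two
      # total route delays into the output unit coincide
      degen <- any(apply(d1, 2L, anyDuplicated) > 0L) ||
        anyDuplicated(as.vector(sweep(d1, 2L, d2, `+`))) > 0L
      if (!degen) break
      if (try == 100L) stopf("could not draw a non-degenerate delay set")
    }
    delays1 <- d1
    delays2 <- d2
  }
  if (!all(dim(weights1) == n_units) || length(weights2) != n_units)
    stopf("weight shapes must be N x N and N")
  structure(list(weights1 = weights1, weights2 = as.numeric(weights2),
                 delays1 = delays1, delays2 = as.numeric(delays2),
                 n_units = n_units, bounds = bounds, lif = lif,
                 resolution_ms = resolution_ms),
            class = c("two_layer_network", "spiking_network"))
}

# Forward pass of a two-layer network on one example.
# Returns per-route (stim event k, hidden h) matrices of first-layer output
# bits and final route bits, the hidden arrival schedule, and the output
# unit's arrival table.
two_layer_forward <- function(net, example) {
  ev <- example$events
  n_stim <- nrow(ev)
  N <- net$n_units
  tau <- net$lif$tau_mem
  vth <- net$lif$v_threshold
  # hidden arrivals: arr_t[k, h] = stim time + delay1[m, h]
  arr_t <- outer(ev$time, rep(1, N)) + net$delays1[ev$unit, , drop = FALSE]
  arr_w <- net$weights1[ev$unit, , drop = FALSE] * ev$amplitude
  o1 <- matrix(0L, n_stim, N)
  spikes_h <- vector("list", N)   # per hidden unit: spike times
  spike_route <- vector("list", N)
  for (h in seq_len(N)) {
    o <- order(arr_t[, h])
    res <- lif_run_cpp(arr_t[o, h], arr_w[o, h], tau, vth)
    o1[o, h] <- res$output
    fired <- o[res$output == 1L]
    spikes_h[[h]] <- arr_t[fired, h]
    spike_route[[h]] <- fired          # stim-event index that triggered
  }
  # output-unit arrivals: one per hidden spike
  hh <- rep(seq_len(N), lengths(spikes_h))
  kk <- unlist(spike_route, use.names = FALSE)
  tt <- unlist(spikes_h, use.names = FALSE) + net$delays2[hh]
  o2 <- integer(0)
  final <- matrix(0L, n_stim, N)
  if (length(tt)) {
    o <- order(tt)
    res <- lif_run_cpp(tt[o], net$weights2[hh[o]], tau, vth)
    o2 <- integer(length(tt))
    o2[o] <- res$output
    final[cbind(kk, hh)] <- o2
  }
  list(o1 = o1, final = final,
       out_arrivals = data.frame(hidden = hh, stim = kk, time = tt,
                                 output = if (length(tt)) o2 else integer(0)),
       hidden_arr_t = arr_t)
}

# STDP adaptation of one weight vector given an arrival schedule:
# weights[idx] of sub-threshold arrivals pair with reference spikes.
adapt_arrivals <- function(weights, idx, times, outputs, ref_spikes,
                           params, bounds) {
  sub <- which(outputs == 0L)
  for (k in sub) {
    f <- pairing_factor(times[k], ref_spikes, params)
    weights[idx[k]] <- clip_bounds(weights[idx[k]] * f, bounds)
  }
  weights
}

#' Present one example to a two-layer teacher-student pair
#'
#' The hidden layer produces its outputs first; those outputs are the input
#' to the output unit.  Both networks adapt their first-layer weights on
#' their own hidden input/output relations; the student's second layer adapts
#' using the teacher's output spike timings together with the student's own
#' sub-threshold arrival timings.  Learning steps are applied per
#' identifiable route: first-layer conflicts update `weights1[m, h]`,
#' second-layer conflicts (routes whose hidden bits agree and spike) update
#' `weights2[h]`.
#'
#' @param pair a [teacher_student_pair()] over [two_layer_network()]s.
#' @param example a multilayer `async_example`.
#' @param record_steps unused placeholder for interface symmetry.
#' @return a list: updated `pair`, per-route final-output bit matrices
#'   `teacher_final` / `student_final`, first-layer bit matrices, `mismatch`
#'   (route-level disagreements of the final bits) and `mismatch_hidden`.
#' @export
present_example_multilayer <- function(pair, example, record_steps = FALSE) {
  if (!inherits(pair$teacher, "two_layer_network"))
    stopf("`pair` must hold two-layer networks")
  tnet <- pair$teacher
  snet <- pair$student
  st <- pair$stdp
  lr <- pair$learning
  bounds <- tnet$bounds
  ev <- example$events
  fT <- two_layer_forward(tnet, example)
  fS <- two_layer_forward(snet, example)

  if (st$enabled) {
    # first layer: each network on its own hidden input/output
    for (h in seq_len(tnet$n_units)) {
      tspk <- fT$hidden_arr_t[fT$o1[, h] == 1L, h]
      tnet$weights1[, h] <- adapt_arrivals(
        tnet$weights1[, h], ev$unit, fT$hidden_arr_t[, h], fT$o1[, h],
        tspk, st, bounds)
      sspk <- fS$hidden_arr_t[fS$o1[, h] == 1L, h]
      snet$weights1[, h] <- adapt_arrivals(
        snet$weights1[, h], ev$unit, fS$hidden_arr_t[, h], fS$o1[, h],
        sspk, st, bounds)
    }
    # second layer: teacher on its own trace; student on the teacher's
    # output spike timings and its own sub-threshold arrivals
    oaT <- fT$out_arrivals
    oaS <- fS$out_arrivals
    tout_spikes <- oaT$time[oaT$output == 1L]
    if (nrow(oaT))
      tnet$weights2 <- adapt_arrivals(tnet$weights2, oaT$hidden, oaT$time,
                                      oaT$output, tout_spikes, st, bounds)
    if (nrow(oaS))
      snet$weights2 <- adapt_arrivals(snet$weights2, oaS$hidden, oaS$time,
                                      oaS$output, tout_spikes, st, bounds)
  }

  # learning on conflicting routes, in arrival-time order
  mismatch_hidden <- 0L
  if (lr$enabled && lr$step_size > 0) {
    conflicts <- which(fT$o1 != fS$o1)
    if (length(conflicts)) {
      ord <- conflicts[order(fT$hidden_arr_t[conflicts])]
      for (idx in ord) {
        k <- (idx - 1L) %% nrow(fT$o1) + 1L
        h <- (idx - 1L) %/% nrow(fT$o1) + 1L
        m <- ev$unit[k]
        snet$weights1[m, h] <- clip_bounds(
          snet$weights1[m, h] +
            lr$step_size * (fT$o1[k, h] - fS$o1[k, h]) * ev$amplitude[k],
          bounds)
      }
    }
    mismatch_hidden <- length(conflicts)
    # second layer: routes that spiked at the hidden layer in both networks
    both <- which(fT$o1 == 1L & fS$o1 == 1L & fT$final != fS$final)
    for (idx in both) {
      k <- (idx - 1L) %% nrow(fT$o1) + 1L
      h <- (idx - 1L) %/% nrow(fT$o1) + 1L
      snet$weights2[h] <- clip_bounds(
        snet$weights2[h] +
          lr$step_size * (fT$final[k, h] - fS$final[k, h]), bounds)
    }
  } else {
    mismatch_hidden <- sum(fT$o1 != fS$o1)
  }

  pair$teacher <- tnet
  pair$student <- snet
  list(pair = pair,
       teacher_final = fT$final, student_final = fS$final,
       teacher_hidden = fT$o1, student_hidden = fS$o1,
       mismatch = sum(fT$final != fS$final),
       mismatch_hidden = mismatch_hidden,
       step_counts = c(attractive = NA_integer_, repulsive = NA_integer_,
                       neutral = NA_integer_))
}
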