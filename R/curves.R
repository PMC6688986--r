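#' Assemble a full run configuration
#'
#' Bundles every knob of a learning-curve experiment.  The master `seed`
#' deterministically derives four independent streams: teacher
#' initialization, student initialization, training examples, and test
#' examples (so the training trajectory is identical with or without
#' evaluation).
#'
#' @param scenario `"synaptic"`, `"dendritic"` or `"multilayer"`.
#' @param n_units N.
#' @param max_p number of training examples.
#' @param stdp an [stdp_params()] object.
#' @param learning a [learning_params()] object.
#' @param schedule an [eval_schedule()] object.
#' @param input an [input_gen_params()] object (`NULL`: scenario default;
#'   the dendritic default carries `weak_fill_amplitude = 0.01`).
#' @param bounds reflecting bounds on the adaptive parameters.
#' @param lif a [lif_params()] object.
#' @param adaptation_source `"teacher"` or `"self"`.
#' @param stop_when_identical stop (after a final measurement) at the first
#'   example where teacher and student adaptive parameters are exactly
#'   identical; default `TRUE` for the dendritic scenario.
#' @param track_frozen keep a 500-example history of each dendritic strength
#'   and report the frozen fraction at each measurement (dendritic only).
#' @param seed master seed (integer).
#' @param label free-text label stored with the curve.
#' @return an object of class `run_config`.
#' @export
curve_config <- function(scenario = c("synaptic", "dendritic", "multilayer"),
                         n_units, max_p,
                         stdp = stdp_params(),
                         learning = learning_params(),
                         schedule = eval_schedule(),
                         input = NULL,
                         bounds = NULL,
                         lif = lif_params(),
                         adaptation_source = "teacher",
                         stop_when_identical = NULL,
                         track_frozen = NULL,
                         seed = 1L, label = "") {
  scenario <- match.arg(scenario)
  if (is.null(bounds))
    bounds <- if (scenario == "dendritic") c(0.1, 2) else c(1e-4, 1.5)
  if (is.null(input)) {
    input <- switch(scenario,
      synaptic = input_gen_params(),
      dendritic = input_gen_params(weak_fill_amplitude = 0.01),
      multilayer = input_gen_params(
        resolution_ms = if (n_units <= 100) 1e-4 else 1e-3))
  }
  if (is.null(stop_when_identical))
    stop_when_identical <- scenario == "dendritic"
  if (is.null(track_frozen)) track_frozen <- scenario == "dendritic"
  structure(list(scenario = scenario, n_units = as.integer(n_units),
                 max_p = as.integer(max_p), stdp = stdp,
                 learning = learning, schedule = schedule, input = input,
                 bounds = bounds, lif = lif,
                 adaptation_source = adaptation_source,
                 stop_when_identical = isTRUE(stop_when_identical),
                 track_frozen = isTRUE(track_frozen),
                 seed = as.integer(seed), label = label),
            class = "run_config")
}

get_rng <- function() get(".Random.seed", envir = globalenv())
set_rng <- function(state) assign(".Random.seed", state, envir = globalenv())

derive_streams <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 4L),
           c("teacher", "student", "train", "test"))
}

build_pair_from_config <- function(config, seeds) {
  set.seed(seeds[["teacher"]])
  teacher <- switch(config$scenario,
    synaptic = synaptic_perceptron(config$n_units, bounds = config$bounds,
                                   lif = config$lif),
    dendritic = dendritic_perceptron(config$n_units,
                                     bounds_J = config$bounds,
                                     lif = config$lif),
    multilayer = two_layer_network(config$n_units, bounds = config$bounds,
                                   lif = config$lif,
                                   resolution_ms = config$input$resolution_ms))
  set.seed(seeds[["student"]])
  teacher_student_pair(teacher, stdp = config$stdp,
                       learning = config$learning,
                       adaptation_source = config$adaptation_source)
}

#' Run a learning-curve experiment
#'
#' Interleaves training (the per-example three-step protocol) with frozen
#' -dynamics generalization-error measurements on a dedicated test stream.
#' Records, per measurement point: `p`, `alpha = p / N`, `eps_g`, `stderr`,
#' the parameter overlap `R`, and (dendritic) the frozen-dendrite fraction.
#' For the dendritic scenario the run stops -- after one final measurement --
#' at the first example where teacher and student strengths are exactly
#' identical (from which point `eps_g` is exactly 0).
#'
#' @param config a [curve_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `learning_curve`: `points` (data frame),
#'   `config`, `seed`, `first_identical_p` (`NA` if never reached),
#'   `step_counts` (total attractive/repulsive/neutral learning steps), and
#'   `max_stderr`.
#' @export
run_learning_curve <- function(config, quiet = TRUE) {
  seeds <- derive_streams(config$seed)
  pair <- build_pair_from_config(config, seeds)
  if (config$scenario == "multilayer")
    return(run_curve_multilayer(config, pair, seeds, quiet))

  st <- config$stdp
  lr <- config$learning
  sch <- config$schedule
  input <- config$input
  N <- config$n_units
  kernel_exp <- as.integer(st$kernel == "exp")
  pair_all <- as.integer(st$pair == "all")
  self <- as.integer(config$adaptation_source == "self")
  rank_mode <- as.integer(st$mode == "rank_window")
  adapt_on <- as.integer(st$enabled)
  learn_on <- as.integer(lr$enabled)
  dendritic <- config$scenario == "dendritic"

  # mutable parameter vectors (the C++ core updates them in place)
  if (dendritic) {
    pT <- pair$teacher$strengths + 0
    pS <- pair$student$strengths + 0
    wfix <- pair$teacher$fixed_weights
    K <- pair$teacher$n_dendrites
  } else {
    pT <- pair$teacher$weights + 0
    pS <- pair$student$weights + 0
  }

  jhist <- if (dendritic && config$track_frozen)
    matrix(NA_real_, 500L, length(pT)) else NULL

  set.seed(seeds[["train"]])

  counts <- c(attractive = 0, repulsive = 0, neutral = 0)
  pts <- list()
  first_identical <- NA_integer_
  identical_now <- FALSE

  measure <- function(p) {
    # swap to the dedicated test stream (a deterministic function of the
    # master seed and p, so measurements are identical whatever the
    # evaluation cadence), measure, swap back
    train_state <- get_rng()
    set.seed((seeds[["test"]] + p) %% 2147483647L)
    reps <- vapply(seq_len(sch$n_repeats), function(r) {
      mism <- 0; tot <- 0
      for (i in seq_len(sch$n_test)) {
        ex <- generate_example_for(config$scenario, N, input)
        ev <- ex$events
        if (dendritic) {
          mism <- mism + eval_dendritic_cpp(
            as.integer(ev$unit) - 1L, ev$time, ev$amplitude,
            as.integer(ev$dendrite) - 1L, wfix, pT, pS,
            config$lif$tau_mem, config$lif$v_threshold)
        } else {
          mism <- mism + eval_synaptic_cpp(
            as.integer(ev$unit) - 1L, ev$time, ev$amplitude, pT, pS,
            config$lif$tau_mem, config$lif$v_threshold)
        }
        tot <- tot + nrow(ev)
      }
      mism / tot
    }, numeric(1))
    set_rng(train_state)
    frozen <- NA_real_
    if (!is.null(jhist) && p >= 500L)
      frozen <- mean(apply(jhist, 2L, stats::var) < 1e-3)
    Rv <- tryCatch(overlap_R(pS, pT), error = function(e) NA_real_)
    data.frame(p = p, alpha = p / N, eps_g = mean(reps),
               stderr = if (sch$n_repeats > 1L)
                 stats::sd(reps) / sqrt(sch$n_repeats) else 0,
               R = Rv, frozen_fraction = frozen)
  }

  for (p in seq_len(config$max_p)) {
    ex <- generate_example_for(config$scenario, N, input)
    ev <- ex$events
    if (dendritic) {
      res <- present_dendritic_cpp(
        as.integer(ev$unit) - 1L, ev$time, ev$amplitude,
        as.integer(ev$dendrite) - 1L, ev$rank, wfix, pT, pS,
        config$lif$tau_mem, config$lif$v_threshold,
        st$amplitude, kernel_exp, st$tau_stdp, st$cutoff_ms,
        rank_mode, st$rank_window, pair_all, self,
        lr$step_size, learn_on, config$bounds[1], config$bounds[2],
        adapt_on, 0L)
    } else {
      res <- present_synaptic_cpp(
        as.integer(ev$unit) - 1L, ev$time, ev$amplitude, pT, pS,
        config$lif$tau_mem, config$lif$v_threshold,
        st$amplitude, kernel_exp, st$tau_stdp, st$cutoff_ms,
        pair_all, self, lr$step_size, learn_on,
        config$bounds[1], config$bounds[2], adapt_on, 0L)
    }
    counts <- counts + c(res$n_attractive, res$n_repulsive, res$n_neutral)
    if (!is.null(jhist)) jhist[(p - 1L) %% 500L + 1L, ] <- pT
    if (is.na(first_identical) && all(pT == pS)) {
      first_identical <- p
      identical_now <- TRUE
    }
    if (identical_now && config$stop_when_identical) {
      pts[[length(pts) + 1L]] <- measure(p)
      if (!quiet) message("parameters identical at p = ", p)
      break
    }
    if (p %% sch$eval_every == 0L || p == config$max_p) {
      pts[[length(pts) + 1L]] <- measure(p)
      if (!quiet) message(sprintf("p = %d, eps_g = %.3g", p,
                                  pts[[length(pts)]]$eps_g))
    }
  }

  pair$teacher <- `adaptive_params<-`(pair$teacher, pT)
  pair$student <- `adaptive_params<-`(pair$student, pS)
  points <- do.call(rbind, pts)
  new_learning_curve(points, config, first_identical, counts, pair)
}

new_learning_curve <- function(points, config, first_identical, counts,
                               pair) {
  structure(list(points = points, config = config, seed = config$seed,
                 first_identical_p = first_identical,
                 step_counts = counts,
                 max_stderr = if (nrow(points)) max(points$stderr) else NA,
                 pair = pair),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve: %s N = %d, %d points, final eps_g = %.4g%s>\n",
              x$config$scenario, x$config$n_units, nrow(x$points),
              x$points$eps_g[nrow(x$points)],
              if (!is.na(x$first_identical_p))
                sprintf(", identical at p = %d", x$first_identical_p)
              else ""))
  invisible(x)
}

run_curve_multilayer <- function(config, pair, seeds, quiet) {
  sch <- config$schedule
  N <- config$n_units
  set.seed(seeds[["train"]])
  pts <- list()
  measure <- function(p) {
    train_state <- get_rng()
    set.seed((seeds[["test"]] + p) %% 2147483647L)
    reps <- vapply(seq_len(sch$n_repeats), function(r) {
      mism <- 0; tot <- 0
      for (i in seq_len(sch$n_test)) {
        ex <- generate_example_for("multilayer", N, config$input)
        mt <- eval_example_pair(pair, ex)
        mism <- mism + mt[1]; tot <- tot + mt[2]
      }
      mism / tot
    }, numeric(1))
    set_rng(train_state)
    data.frame(p = p, alpha = p / N, eps_g = mean(reps),
               stderr = if (sch$n_repeats > 1L)
                 stats::sd(reps) / sqrt(sch$n_repeats) else 0,
               R = NA_real_, frozen_fraction = NA_real_)
  }
  for (p in seq_len(config$max_p)) {
    ex <- generate_example_for("multilayer", N, config$input)
    res <- present_example_multilayer(pair, ex)
    pair <- res$pair
    if (p %% sch$eval_every == 0L || p == config$max_p)
      pts[[length(pts) + 1L]] <- measure(p)
  }
  new_learning_curve(do.call(rbind, pts), config, NA_integer_,
                     c(attractive = NA, repulsive = NA, neutral = NA), pair)
}
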