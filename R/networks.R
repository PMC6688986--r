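#' Construct a synaptic perceptron
#'
#' N input units feed one LIF output unit through adaptive weights `w`.
#' Default initialization draws the weights uniformly on `init_range` and
#' rescales them to mean `init_mean` (0.5).
#'
#' @param n_units number of input units N.
#' @param weights optional explicit weight vector (length N, within bounds).
#' @param bounds reflecting weight bounds (default `c(1e-4, 1.5)`).
#' @param lif a [lif_params()] object.
#' @param init_range,init_mean initialization: uniform on `init_range`,
#'   rescaled to mean `init_mean` (set `init_mean = NULL` to skip rescaling).
#' @return an object of class `synaptic_perceptron`.
#' @export
synaptic_perceptron <- function(n_units, weights = NULL,
                                bounds = c(1e-4, 1.5), lif = lif_params(),
                                init_range = c(0.1, 0.9), init_mean = 0.5) {
  n_units <- as.integer(n_units)
  if (is.null(weights)) {
    weights <- runif(n_units, init_range[1], init_range[2])
    if (!is.null(init_mean)) weights <- weights * init_mean / mean(weights)
  }
  if (length(weights) != n_units) stopf("`weights` must have length N")
  if (any(weights < bounds[1]) || any(weights > bounds[2]))
    stopf("initial weights outside bounds")
  structure(list(weights = as.numeric(weights), n_units = n_units,
                 bounds = bounds, lif = lif),
            class = c("synaptic_perceptron", "spiking_network"))
}

#' Construct a dendritic perceptron
#'
#' N input units wired in fives to K = N/5 dendrites.  The dendritic
#' strengths `J` are the adaptive parameters; the synaptic weights `w` are
#' fixed architecture, shared between teacher and student.
#'
#' @param n_units number of input units N (divisible by 10).
#' @param strengths optional explicit J vector (length K, within `bounds_J`);
#'   default uniform on `init_range_J`.
#' @param fixed_weights optional explicit fixed weight vector (length N);
#'   default uniform on `c(0.1, 0.9)` rescaled to mean 0.5.
#' @param bounds_J reflecting bounds on J (default `c(0.1, 2)`).
#' @param lif a [lif_params()] object.
#' @param init_range_J initialization range for J (default `c(0.5, 1.5)`).
#' @return an object of class `dendritic_perceptron`.
#' @export
dendritic_perceptron <- function(n_units, strengths = NULL,
                                 fixed_weights = NULL,
                                 bounds_J = c(0.1, 2), lif = lif_params(),
                                 init_range_J = c(0.5, 1.5)) {
  n_units <- as.integer(n_units)
  if (n_units %% 10L != 0L) stopf("`n_units` must be divisible by 10")
  K <- n_units %/% 5L
  if (is.null(fixed_weights)) {
    fixed_weights <- runif(n_units, 0.1, 0.9)
    fixed_weights <- fixed_weights * 0.5 / mean(fixed_weights)
  }
  if (is.null(strengths))
    strengths <- runif(K, init_range_J[1], init_range_J[2])
  if (length(strengths) != K) stopf("`strengths` must have length K = N/5")
  if (length(fixed_weights) != n_units)
    stopf("`fixed_weights` must have length N")
  if (any(strengths < bounds_J[1]) || any(strengths > bounds_J[2]))
    stopf("initial strengths outside bounds")
  structure(list(strengths = as.numeric(strengths),
                 fixed_weights = as.numeric(fixed_weights),
                 n_units = n_units, n_dendrites = K,
                 bounds = bounds_J, lif = lif),
            class = c("dendritic_perceptron", "spiking_network"))
}

#' Per-event effective drives of a network on an example
#'
#' `w * x` for the synaptic perceptron, `J * w * x` for the dendritic one.
#'
#' @param net a `spiking_network`.
#' @param example an `async_example` of the matching scenario.
#' @return numeric drive vector, one per event.
#' @export
network_drives <- function(net, example) {
  ev <- example$events
  if (inherits(net, "dendritic_perceptron")) {
    net$strengths[ev$dendrite] * net$fixed_weights[ev$unit] * ev$amplitude
  } else {
    net$weights[ev$unit] * ev$amplitude
  }
}

#' Response of a single network to one example
#'
#' @inheritParams network_drives
#' @return an `output_trace` (see [lif_run()]).
#' @export
network_response <- function(net, example) {
  lif_run(example, network_drives(net, example), net$lif)
}

adaptive_params <- function(net) {
  if (inherits(net, "dendritic_perceptron")) net$strengths else net$weights
}

`adaptive_params<-` <- function(net, value) {
  if (inherits(net, "dendritic_perceptron")) net$strengths <- value
  else net$weights <- value
  net
}

#' Construct a teacher-student pair
#'
#' Teacher and student must share the same architecture (same N; for the
#' dendritic scenario the fixed weights are copied from the teacher; for the
#' two-layer scenario the delays are copied from the teacher).  If `student`
#' is `NULL` it is drawn independently from the same initialization as the
#' teacher.
#'
#' @param teacher,student `spiking_network` objects of the same class.
#' @param stdp an [stdp_params()] object.
#' @param learning a [learning_params()] object.
#' @param adaptation_source `"teacher"` (the student repeats the teacher's
#'   adaptation factors, the default) or `"self"` (the student adapts on its
#'   own trace).
#' @return an object of class `teacher_student_pair`.
#' @export
teacher_student_pair <- function(teacher, student = NULL,
                                 stdp = stdp_params(),
                                 learning = learning_params(),
                                 adaptation_source = c("teacher", "self")) {
  adaptation_source <- match.arg(adaptation_source)
  if (is.null(student)) {
    student <- if (inherits(teacher, "dendritic_perceptron")) {
      dendritic_perceptron(teacher$n_units,
                           fixed_weights = teacher$fixed_weights,
                           bounds_J = teacher$bounds, lif = teacher$lif)
    } else if (inherits(teacher, "two_layer_network")) {
      two_layer_network(teacher$n_units, delays1 = teacher$delays1,
                        delays2 = teacher$delays2, bounds = teacher$bounds,
                        lif = teacher$lif)
    } else {
      synaptic_perceptron(teacher$n_units, bounds = teacher$bounds,
                          lif = teacher$lif)
    }
  }
  if (!identical(class(teacher), class(student)))
    stopf("teacher and student must have the same scenario class")
  if (teacher$n_units != student$n_units)
    stopf("teacher and student must have the same N")
  if (inherits(teacher, "dendritic_perceptron") &&
      !identical(teacher$fixed_weights, student$fixed_weights))
    stopf("dendritic fixed weights are architecture and must be shared")
  if (inherits(teacher, "two_layer_network") &&
      !(identical(teacher$delays1, student$delays1) &&
        identical(teacher$delays2, student$delays2)))
    stopf("two-layer delays are architecture and must be shared")
  structure(list(teacher = teacher, student = student, stdp = stdp,
                 learning = learning,
                 adaptation_source = adaptation_source),
            class = "teacher_student_pair")
}

scenario_of <- function(net) {
  if (inherits(net, "dendritic_perceptron")) "dendritic"
  else if (inherits(net, "two_layer_network")) "multilayer"
  else "synaptic"
}

#' Present one example to a teacher-student pair
#'
#' Runs the three-step protocol: (1) teacher output production and
#' self-adaptation, (2) student output production and adaptation (following
#' the teacher's trace by default), (3) learning steps on the student's
#' parameters at events with conflicting outputs.  Functional semantics: the
#' updated pair is returned, the input pair is unchanged.
#'
#' @param pair a [teacher_student_pair()].
#' @param example an `async_example` matching the pair's scenario.
#' @param record_steps if `TRUE`, return a data frame of per-step records
#'   (Eq.-style attractive/repulsive bookkeeping).
#' @return a list: `pair` (updated), `teacher_trace`, `student_trace`,
#'   `mismatch` (number of events with conflicting outputs), `step_counts`
#'   (attractive/repulsive/neutral learning steps) and, when requested,
#'   `steps`.
#' @export
present_example <- function(pair, example, record_steps = FALSE) {
  if (scenario_of(pair$teacher) != example$scenario)
    stopf("example scenario '%s' does not match pair scenario '%s'",
          example$scenario, scenario_of(pair$teacher))
  if (example$scenario == "multilayer")
    return(present_example_multilayer(pair, example,
                                      record_steps = record_steps))
  ev <- example$events
  st <- pair$stdp
  lr <- pair$learning
  kernel_exp <- as.integer(st$kernel == "exp")
  pair_all <- as.integer(st$pair == "all")
  self <- as.integer(pair$adaptation_source == "self")
  if (example$scenario == "dendritic") {
    JT <- pair$teacher$strengths + 0   # force copies: C++ mutates in place
    JS <- pair$student$strengths + 0
    res <- present_dendritic_cpp(
      as.integer(ev$unit) - 1L, ev$time, ev$amplitude,
      as.integer(ev$dendrite) - 1L, ev$rank,
      pair$teacher$fixed_weights, JT, JS,
      pair$teacher$lif$tau_mem, pair$teacher$lif$v_threshold,
      st$amplitude, kernel_exp, st$tau_stdp, st$cutoff_ms,
      as.integer(st$mode == "rank_window"), st$rank_window, pair_all, self,
      lr$step_size, as.integer(lr$enabled),
      pair$teacher$bounds[1], pair$teacher$bounds[2],
      as.integer(st$enabled), as.integer(record_steps))
    pair$teacher$strengths <- JT
    pair$student$strengths <- JS
    dendr <- ev$dendrite
  } else {
    wT <- pair$teacher$weights + 0
    wS <- pair$student$weights + 0
    res <- present_synaptic_cpp(
      as.integer(ev$unit) - 1L, ev$time, ev$amplitude, wT, wS,
      pair$teacher$lif$tau_mem, pair$teacher$lif$v_threshold,
      st$amplitude, kernel_exp, st$tau_stdp, st$cutoff_ms, pair_all, self,
      lr$step_size, as.integer(lr$enabled),
      pair$teacher$bounds[1], pair$teacher$bounds[2],
      as.integer(st$enabled), as.integer(record_steps))
    pair$teacher$weights <- wT
    pair$student$weights <- wS
    dendr <- NULL
  }
  out <- list(
    pair = pair,
    teacher_trace = new_output_trace(res$o_teacher, ev$time,
                                     dendrite = dendr),
    student_trace = new_output_trace(res$o_student, ev$time,
                                     dendrite = dendr),
    mismatch = res$mismatch,
    step_counts = c(attractive = res$n_attractive,
                    repulsive = res$n_repulsive,
                    neutral = res$n_neutral))
  if (record_steps) out$steps <- as.data.frame(res$steps)
  out
}
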