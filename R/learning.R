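#' Learning-rule parameters
#'
#' The learning step is the gradient of an output-mismatch cost with respect
#' to the student parameter, reduced (with the exponential voltage prefactor
#' dropped, the default) to the perceptron-like rule
#' `param + step_size * (O_T - O_S) * x`.
#'
#' @param step_size the learning step size lambda (non-negative).
#' @param enabled if `FALSE`, learning steps are skipped entirely (adaptation
#'   -only dynamics).
#' @param drop_exponential_prefactor keep the default `TRUE` to use the
#'   simplified rule; `FALSE` multiplies the amplitude by
#'   `exp(lag_ms / tau_mem)` where `lag_ms` is the lag between the compared
#'   output time and the stimulation (zero in the per-event protocol, where
#'   outputs are compared at the stimulation instant itself).
#' @return an object of class `learning_params`.
#' @export
learning_params <- function(step_size = 0.001, enabled = TRUE,
                            drop_exponential_prefactor = TRUE) {
  check_scalar_number(step_size, "step_size")
  if (step_size < 0) stopf("`step_size` must be >= 0")
  structure(list(step_size = step_size, enabled = isTRUE(enabled),
                 drop_exponential_prefactor =
                   isTRUE(drop_exponential_prefactor)),
            class = "learning_params")
}

#' One mismatch-driven learning step
#'
#' Applied only when the teacher and student outputs at an event conflict;
#' moves the student parameter by `step_size * (o_teacher - o_student) *
#' amplitude` and clips it into `bounds`.
#'
#' @param param current student parameter value (weight or dendritic
#'   strength).
#' @param o_teacher,o_student binary outputs (0/1) at the event.
#' @param amplitude stimulation amplitude `x` at the event.
#' @param params a [learning_params()] object.
#' @param bounds length-2 vector of parameter bounds.
#' @param lag_ms,tau_mem only used when the exponential prefactor is kept.
#' @return the updated parameter value.
#' @export
learning_step <- function(param, o_teacher, o_student, amplitude,
                          params = learning_params(),
                          bounds = c(1e-4, 1.5), lag_ms = 0, tau_mem = 20) {
  if (!all(c(o_teacher, o_student) %in% c(0, 1)))
    stopf("outputs must be 0 or 1")
  if (!params$enabled || o_teacher == o_student) return(param)
  x <- amplitude
  if (!params$drop_exponential_prefactor) x <- x * exp(lag_ms / tau_mem)
  clip_bounds(param + params$step_size * (o_teacher - o_student) * x, bounds)
}

#' Classify a learning step as attractive, repulsive or neutral
#'
#' A step is attractive when it moves the student parameter toward the
#' teacher's value at the previous example: the product
#' `(teacher_before - student_before) * (student_after - student_pre)` is
#' positive.  `teacher_before` and `student_before` are snapshots at the
#' start of the example; `student_pre`/`student_after` bracket the learning
#' step itself (by default `student_pre = student_before`).
#'
#' @param teacher_before teacher parameter at the start of the example.
#' @param student_before student parameter at the start of the example.
#' @param student_after student parameter after the learning step.
#' @param student_pre student parameter immediately before the learning step.
#' @return `"attractive"`, `"repulsive"` or `"neutral"` (zero product).
#' @export
classify_step <- function(teacher_before, student_before, student_after,
                          student_pre = student_before) {
  prod <- (teacher_before - student_before) * (student_after - student_pre)
  if (prod > 0) "attractive" else if (prod < 0) "repulsive" else "neutral"
}
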