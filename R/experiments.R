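#' Evaluation schedule for generalization-error measurements
#'
#' @param eval_every number of training examples between measurements
#'   (2000 for the synaptic/multilayer scenarios, 1000 for the dendritic).
#' @param n_test number of fresh test examples per measurement repeat.  The
#'   reference protocol uses up to 250,000; the desk-scale default is 10,000.
#' @param n_repeats number of measurement repetitions (>= 3); each point
#'   stores the mean and the spread of the repeats.
#' @return an object of class `eval_schedule`.
#' @export
eval_schedule <- function(eval_every = 2000, n_test = 10000,
                          n_repeats = 3) {
  if (eval_every < 1 || n_test < 1 || n_repeats < 1)
    stopf("schedule fields must be positive")
  structure(list(eval_every = as.integer(eval_every),
                 n_test = as.integer(n_test),
                 n_repeats = as.integer(n_repeats)),
            class = "eval_schedule")
}

generate_example_for <- function(scenario, n_units, input) {
  switch(scenario,
         synaptic = generate_synaptic_example(n_units, input),
         dendritic = generate_dendritic_example(n_units, input),
         multilayer = generate_multilayer_example(n_units, input),
         stopf("unknown scenario '%s'", scenario))
}

# mismatch count and number of compared stimulations for one frozen example
eval_example_pair <- function(pair, example) {
  ev <- example$events
  t <- pair$teacher
  s <- pair$student
  if (example$scenario == "dendritic") {
    m <- eval_dendritic_cpp(as.integer(ev$unit) - 1L, ev$time, ev$amplitude,
                            as.integer(ev$dendrite) - 1L, t$fixed_weights,
                            t$strengths, s$strengths,
                            t$lif$tau_mem, t$lif$v_threshold)
    c(m, nrow(ev))
  } else if (example$scenario == "multilayer") {
    fT <- two_layer_forward(t, example)
    fS <- two_layer_forward(s, example)
    # denominator: the stated upper bound N^2/2 routes per input
    c(sum(fT$final != fS$final), t$n_units^2 / 2)
  } else {
    m <- eval_synaptic_cpp(as.integer(ev$unit) - 1L, ev$time, ev$amplitude,
                           t$weights, s$weights,
                           t$lif$tau_mem, t$lif$v_threshold)
    c(m, nrow(ev))
  }
}

#' Measure the generalization error of a frozen teacher-student pair
#'
#' Presents fresh random test examples to both networks with adaptation and
#' learning switched off and returns the fraction of stimulations with
#' conflicting outputs (mismatch firings / total stimulations).  Repeated
#' `n_repeats` times; the standard error over repeats is reported.
#'
#' @param pair a [teacher_student_pair()]; its parameters are not modified.
#' @param schedule an [eval_schedule()] (only `n_test` and `n_repeats` are
#'   used).
#' @param input an [input_gen_params()] object for the test examples.
#' @return a list: `eps_g` (mean), `stderr`, `repeats` (per-repeat values).
#' @export
generalization_error <- function(pair, schedule = eval_schedule(),
                                 input = input_gen_params()) {
  scen <- scenario_of(pair$teacher)
  reps <- vapply(seq_len(schedule$n_repeats), function(r) {
    mism <- 0
    tot <- 0
    for (i in seq_len(schedule$n_test)) {
      ex <- generate_example_for(scen, pair$teacher$n_units, input)
      mt <- eval_example_pair(pair, ex)
      mism <- mism + mt[1]
      tot <- tot + mt[2]
    }
    mism / tot
  }, numeric(1))
  list(eps_g = mean(reps),
       stderr = if (length(reps) > 1L) stats::sd(reps) / sqrt(length(reps))
                else 0,
       repeats = reps)
}

#' Normalized overlap between student and teacher parameter vectors
#'
#' The cosine similarity of the parameter vectors shifted by the spiking
#' threshold: `R = ((s - 1) . (t - 1)) / (||s - 1|| ||t - 1||)`.  Applies to
#' synaptic weights or to dendritic strengths alike.
#'
#' @param student_params,teacher_params numeric vectors of equal length.
#' @param center the shift (default 1, the scaled threshold).
#' @return R in `[-1, 1]`.
#' @export
overlap_R <- function(student_params, teacher_params, center = 1) {
  if (length(student_params) != length(teacher_params))
    stopf("parameter vectors must have the same length")
  s <- student_params - center
  t <- teacher_params - center
  ns <- sqrt(sum(s^2))
  nt <- sqrt(sum(t^2))
  if (ns == 0 || nt == 0)
    stopf("overlap undefined: a shifted parameter vector has zero norm")
  max(-1, min(1, sum(s * t) / (ns * nt)))
}

#' Synchronous-perceptron error predicted from the overlap
#'
#' `eps_g = acos(R) / pi`: the baseline the asynchronous curves are compared
#' against.  Strictly decreasing in R; 0 at R = 1 and 1 at R = -1.
#'
#' @param R overlap in `[-1, 1]` (values beyond by less than 1e-12 are
#'   clamped).
#' @return the predicted generalization error.
#' @export
eps_from_overlap <- function(R) {
  if (any(R > 1 + 1e-12) || any(R < -1 - 1e-12))
    stopf("`R` must lie in [-1, 1]")
  acos(pmin(1, pmax(-1, R))) / pi
}

#' Detect a frozen dendritic strength
#'
#' A dendrite is frozen when all its effective weights are above threshold,
#' so every stimulation evokes a spike and adaptation stops.  Operationally:
#' the variance of its strength over the last `window` examples is below
#' `threshold`.
#'
#' @param history numeric vector of one strength's recent values.
#' @param threshold variance bound (default 1e-3).
#' @param window required history length (default 500); shorter histories are
#'   not assessable and return `NA`.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
detect_frozen <- function(history, threshold = 1e-3, window = 500) {
  if (length(history) < window) return(NA)
  h <- history[(length(history) - window + 1L):length(history)]
  stats::var(h) < threshold
}

#' Weight value above which a single stimulation always fires
#'
#' With amplitudes bounded below by `min_amplitude`, any weight above
#' `v_threshold / min_amplitude` (1 / 0.8 = 1.25 at the defaults) evokes a
#' spike on every stimulation; its exact value is behaviorally irrelevant.
#'
#' @param lif a [lif_params()] object.
#' @param min_amplitude lower bound of the stimulation amplitudes.
#' @return the firing threshold on the weight axis.
#' @export
weight_firing_threshold <- function(lif = lif_params(),
                                    min_amplitude = 0.8) {
  lif$v_threshold / min_amplitude
}

#' Fit a power-law decay exponent to a stretch of a learning curve
#'
#' Least-squares slope of `log(eps_g)` against `log(p)` over `fit_range`,
#' negated so that a decaying curve yields a positive exponent.  Points with
#' `eps_g = 0` are excluded (log undefined).
#'
#' @param curve a `learning_curve`, or a data frame with columns `p` and
#'   `eps_g`.
#' @param fit_range length-2 vector `[p_lo, p_hi]` (inclusive).
#' @return an object of class `curve_fit`: `exponent`, `fit_range`,
#'   `goodness` (r squared of the log-log fit), `n_points`.
#' @export
fit_power_exponent <- function(curve, fit_range) {
  pts <- if (inherits(curve, "learning_curve")) curve$points else curve
  sel <- pts$p >= fit_range[1] & pts$p <= fit_range[2] & pts$eps_g > 0
  d <- pts[sel, , drop = FALSE]
  if (nrow(d) < 2L)
    stopf("need at least 2 positive points in the fit range")
  fit <- lm(log(eps_g) ~ log(p), data = d)
  # suppressed: lm warns on numerically perfect fits (exact power laws)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(exponent = -unname(coef(fit)[2]),
                 fit_range = fit_range,
                 goodness = r2,
                 n_points = nrow(d)),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit: exponent %.3f over p in [%g, %g], r2 = %.3f, %d points>\n",
              x$exponent, x$fit_range[1], x$fit_range[2], x$goodness,
              x$n_points))
  invisible(x)
}
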