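# Named parameter sets of the reference experimental protocols, so no
# magic numbers live in analysis code.  "-small"/"-mid" variants are the same
# dynamics at desk-scale N.

preset_table <- function() {
  list(
    # synaptic scenario: A = 0.003, lambda = 1/1000, w in [1e-4, 1.5]
    "synaptic-ref" = list(scenario = "synaptic", n_units = 1000L, max_p = 60000L,
                  A = 0.003, lambda = 1e-3, eval_every = 2000L),
    "synaptic-small" = list(scenario = "synaptic", n_units = 100L,
                        max_p = 40000L, A = 0.003, lambda = 1e-3,
                        eval_every = 2000L),
    "synaptic-mid" = list(scenario = "synaptic", n_units = 300L,
                      max_p = 40000L, A = 0.003, lambda = 1e-3,
                      eval_every = 2000L),
    # dendritic, rank-window adaptation, weak-fill inputs, J in [0.1, 2],
    # lambda = 1/N; stops when J^T == J^S exactly
    "dendritic-ref" = list(scenario = "dendritic", n_units = 1000L, max_p = 200000L,
                   A = 0.003, lambda = 1 / 1000, eval_every = 1000L,
                   bounds = c(0.1, 2), weak_fill = 0.01,
                   mode = "rank_window"),
    "dendritic-small" = list(scenario = "dendritic", n_units = 100L,
                         max_p = 300000L, A = 0.003, lambda = 1 / 100,
                         eval_every = 1000L, bounds = c(0.1, 2),
                         weak_fill = 0.01, mode = "rank_window"),
    # dendritic with strong adaptation, J in [0.1, 2.5], no weak fill
    "dendritic-strong" = list(scenario = "dendritic", n_units = 1000L,
                    max_p = 200000L, A = 0.05, lambda = 1 / 1000,
                    eval_every = 1000L, bounds = c(0.1, 2.5),
                    weak_fill = NULL, mode = "rank_window"),
    "dendritic-strong-small" = list(scenario = "dendritic", n_units = 100L,
                          max_p = 100000L, A = 0.05, lambda = 1 / 100,
                          eval_every = 1000L, bounds = c(0.1, 2.5),
                          weak_fill = NULL, mode = "rank_window"),
    # one hidden layer: A = 0.001, lambda = 0.002
    "multilayer-ref" = list(scenario = "multilayer", n_units = 100L, max_p = 20000L,
                  A = 0.001, lambda = 0.002, eval_every = 2000L),
    "multilayer-small" = list(scenario = "multilayer", n_units = 10L,
                        max_p = 2000L, A = 0.001, lambda = 0.002,
                        eval_every = 500L),
    # supplementary variants
    "synaptic-fast" = list(scenario = "synaptic", n_units = 1000L,
                           max_p = 60000L, A = 0.001, lambda = 50 / 1000,
                           eval_every = 2000L),
    "dendritic-slow" = list(scenario = "dendritic", n_units = 1000L,
                            max_p = 200000L, A = 0.003, lambda = 1e-3,
                            eval_every = 1000L, bounds = c(0.1, 2),
                            weak_fill = 0.01, mode = "rank_window"))
}

#' Build a run configuration from a named preset
#'
#' Presets encode the parameter sets of the reference experimental protocols
#' (adaptation amplitude, learning step size, bounds, evaluation cadence);
#' `...` overrides any [curve_config()] argument, e.g. `seed`, `max_p` or
#' `schedule`.
#'
#' @param name one of `"synaptic-ref"`, `"synaptic-small"`, `"synaptic-mid"`, `"dendritic-ref"`,
#'   `"dendritic-small"`, `"dendritic-strong"`, `"dendritic-strong-small"`, `"multilayer-ref"`,
#'   `"multilayer-small"`, `"synaptic-fast"`, `"dendritic-slow"`.
#' @param ... overrides passed to [curve_config()].
#' @return a `run_config`.
#' @export
preset_config <- function(name, ...) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stopf("unknown preset '%s'; available: %s", name,
          paste(names(tab), collapse = ", "))
  p <- tab[[name]]
  mode <- if (is.null(p$mode)) "time_window" else p$mode
  input <- if (p$scenario == "dendritic") {
    input_gen_params(weak_fill_amplitude = p$weak_fill)
  } else if (p$scenario == "multilayer") {
    input_gen_params(resolution_ms = if (p$n_units <= 100L) 1e-4 else 1e-3)
  } else {
    input_gen_params()
  }
  args <- list(scenario = p$scenario, n_units = p$n_units, max_p = p$max_p,
               stdp = stdp_params(amplitude = p$A, mode = mode),
               learning = learning_params(step_size = p$lambda),
               schedule = eval_schedule(eval_every = p$eval_every),
               input = input,
               bounds = if (is.null(p$bounds)) NULL else p$bounds,
               label = name)
  over <- list(...)
  args[names(over)] <- over
  do.call(curve_config, args)
}
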