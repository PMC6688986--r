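#' Serialize an asynchronous example to TSV or JSON
#'
#' The TSV form is line-oriented with one stimulation event per row (columns
#' `unit`, `time`, `amplitude`, plus `dendrite` and `rank` for dendritic
#' examples); metadata travel in `# key: value` header comments.  Round-trips
#' are exact: numbers are written with 17 significant digits.
#'
#' @param example an `async_example`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
example_to_tsv <- function(example, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scenario: %s", example$scenario), con)
  writeLines(sprintf("# n_units: %d", example$n_units), con)
  if (!is.null(example$n_dendrites))
    writeLines(sprintf("# n_dendrites: %d", example$n_dendrites), con)
  ev <- example$events
  fmt <- vapply(ev, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.17g", col)
    else as.character(col)
  }, character(nrow(ev)))
  if (nrow(ev) == 1L) fmt <- matrix(fmt, nrow = 1L)
  writeLines(paste(colnames(ev), collapse = "\t"), con)
  writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname example_to_tsv
#' @export
example_from_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!startsWith(lines, "# ")]
  ev <- read.table(text = body, header = TRUE, sep = "\t",
                   colClasses = NA, stringsAsFactors = FALSE)
  ev$unit <- as.integer(ev$unit)
  ex <- new_async_example(ev, as.integer(meta$n_units), meta$scenario,
                          n_dendrites = if (!is.null(meta$n_dendrites))
                            as.integer(meta$n_dendrites))
  ex
}

#' @rdname example_to_tsv
#' @export
example_to_json <- function(example, path) {
  x <- list(scenario = example$scenario, n_units = example$n_units,
            n_dendrites = example$n_dendrites,
            dendrite_order = example$dendrite_order,
            events = example$events)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname example_to_tsv
#' @export
example_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(x$events)
  ev$unit <- as.integer(ev$unit)
  dord <- x$dendrite_order
  if (!is.null(dord)) dord <- unlist(dord)
  new_async_example(ev, as.integer(x$n_units), x$scenario,
                    n_dendrites = if (!is.null(x$n_dendrites))
                      as.integer(x$n_dendrites),
                    dendrite_order = dord)
}

#' Serialize an output trace to TSV
#'
#' One row per stimulation event: `event_index`, `time_ms`, `output_bit`.
#'
#' @param trace an `output_trace` (see [lif_run()]).
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
trace_to_tsv <- function(trace, path) {
  df <- data.frame(event_index = seq_along(trace$per_event_output),
                   time_ms = trace$times,
                   output_bit = trace$per_event_output)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a learning curve to CSV
#'
#' Columns: `p`, `alpha`, `eps_g`, `stderr`, `R`, `frozen_fraction`.
#'
#' @param curve a `learning_curve` (see [run_learning_curve()]).
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
curve_to_csv <- function(curve, path) {
  write.table(curve$points, path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
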