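#' Multi-sweep current trace
#'
#' Container for simulated or measured current-density recordings: a shared
#' sample-time vector (ms), one current column per sweep (pA/pF), the per-
#' sweep step voltages, and provenance metadata.
#'
#' @param time numeric vector of sample times in ms (strictly increasing)
#' @param current numeric matrix, `length(time)` rows, one column per sweep
#' @param step_voltages per-sweep step voltages in mV
#' @param sample_interval sampling interval in ms
#' @param source `"synthetic"` or `"measured"`
#' @param model_id generating model id for synthetic traces (or `NA`)
#' @param meta optional list of extra metadata (e.g. generating parameters,
#'   noise specification)
#' @return an object of class `"current_trace"`
#' @export
current_trace <- function(time, current, step_voltages, sample_interval,
                          source = c("synthetic", "measured"),
                          model_id = NA_character_, meta = list()) {
  source <- match.arg(source)
  current <- as.matrix(current)
  stopifnot(is.numeric(time), nrow(current) == length(time),
            ncol(current) == length(step_voltages),
            all(diff(time) > 0))
  structure(list(time = time, current = current,
                 step_voltages = as.numeric(step_voltages),
                 sample_interval = sample_interval, source = source,
                 model_id = model_id, meta = meta),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current trace (%s%s): %d sweeps x %d samples, dt = %g ms\n",
              x$source, if (!is.na(x$model_id)) paste0(", ", x$model_id) else "",
              ncol(x$current), nrow(x$current), x$sample_interval))
  invisible(x)
}

#' @export
dim.current_trace <- function(x) dim(x$current)

# grids must match exactly for residual/error computations
check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$time, b$time)) ||
      !identical(dim(a$current), dim(b$current))) {
    stop("traces are defined on different sample grids")
  }
  invisible(TRUE)
}

#' Read and write delimited current-trace files
#'
#' One CSV per recording: column 1 is `time_ms`, columns 2..N+1 are current
#' density in pA/pF for sweeps 1..N. The header row carries the step voltage
#' of each sweep (`V_<mV>`). The reader accepts any uniform sample interval,
#' in particular the 1.5-5 ms spacings typical of patch-clamp exports.
#'
#' @param trace a [current_trace()]
#' @param path file path
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a [current_trace()] with `source = "measured"` unless the file
#'   was written from a synthetic trace.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_ms = trace$time, trace$current)
  names(df)[-1L] <- paste0("V_", trace$step_voltages)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param source provenance label to attach on read
#' @export
read_trace_csv <- function(path, source = "measured") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("trace file needs a time column and >= 1 sweep")
  time <- df[[1L]]
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * max(dt)) {
    stop("trace file must have a uniform, strictly increasing time grid")
  }
  volts <- suppressWarnings(as.numeric(sub("^V_", "", names(df)[-1L])))
  if (anyNA(volts)) volts <- rep(NA_real_, ncol(df) - 1L)
  current_trace(time = time, current = as.matrix(df[-1L]),
                step_voltages = volts, sample_interval = dt[[1L]],
                source = source)
}
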