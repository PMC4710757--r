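#' Voltage-clamp protocol objects
#'
#' A step voltage-clamp protocol is a set of sweeps, each a sequence of
#' constant-voltage segments sampled on a common regular time grid. Samples
#' are taken at `t = 0, dt, 2*dt, ...` up to and including the total sweep
#' duration; a sample falling exactly on a segment boundary is attributed to
#' the segment that starts there (the command voltage has already stepped),
#' while the gating variables are continuous across the boundary.
#'
#' @param duration segment duration in ms (finite, > 0)
#' @param voltage command voltage in mV (finite)
#' @return `voltage_step()` returns a list with elements `duration` and
#'   `voltage`.
#' @export
voltage_step <- function(duration, voltage) {
  stopifnot(is.numeric(duration), length(duration) == 1L, is.finite(duration),
            duration > 0, is.numeric(voltage), length(voltage) == 1L,
            is.finite(voltage))
  list(duration = duration, voltage = voltage)
}

#' @rdname voltage_step
#' @param steps list of `voltage_step()` segments (at least one)
#' @param sample_interval sampling interval in ms (> 0)
#' @return `sweep_protocol()` returns an object of class `"sweep_protocol"`
#'   with numeric vectors `durations` and `voltages` plus the sample interval.
#' @export
sweep_protocol <- function(steps, sample_interval = 2) {
  stopifnot(length(steps) >= 1L, is.numeric(sample_interval),
            length(sample_interval) == 1L, is.finite(sample_interval),
            sample_interval > 0)
  durations <- vapply(steps, function(s) s$duration, numeric(1))
  voltages <- vapply(steps, function(s) s$voltage, numeric(1))
  structure(list(durations = durations, voltages = voltages,
                 sample_interval = sample_interval),
            class = "sweep_protocol")
}

#' @rdname voltage_step
#' @param sweeps list of `sweep_protocol()` objects sharing one sample interval
#' @return `clamp_protocol()` returns an object of class `"clamp_protocol"`.
#' @export
clamp_protocol <- function(sweeps) {
  stopifnot(length(sweeps) >= 1L)
  si <- vapply(sweeps, function(s) s$sample_interval, numeric(1))
  if (length(unique(si)) != 1L) {
    stop("all sweeps must share the same sample_interval")
  }
  structure(list(sweeps = sweeps, sample_interval = si[[1L]]),
            class = "clamp_protocol")
}

#' Standard 13-sweep activation/deactivation protocol
#'
#' Each sweep holds 20 ms at -80 mV, steps for 400 ms to one of 13 test
#' voltages from -70 mV to +50 mV in 10 mV increments, and closes with 400 ms
#' at -110 mV. Sampling every 2 ms gives 411 samples per 820 ms sweep
#' (inclusive of t = 0) and a total protocol length of 13 x 0.82 s = 10.66 s.
#'
#' @param sample_interval sampling interval in ms
#' @return a `clamp_protocol` with 13 sweeps
#' @export
standard_protocol <- function(sample_interval = 2) {
  steps_for <- function(v_step) {
    list(voltage_step(20, -80), voltage_step(400, v_step),
         voltage_step(400, -110))
  }
  sweeps <- lapply(seq(-70, 50, by = 10),
                   function(v) sweep_protocol(steps_for(v), sample_interval))
  clamp_protocol(sweeps)
}

#' @export
print.clamp_protocol <- function(x, ...) {
  cat(sprintf("clamp protocol: %d sweep(s), dt = %g ms, total %g ms\n",
              length(x$sweeps), x$sample_interval,
              sum(vapply(x$sweeps, function(s) sum(s$durations), numeric(1)))))
  invisible(x)
}

# Sample times of one sweep (t = 0 inclusive, end inclusive).
sweep_sample_times <- function(sweep) {
  total <- sum(sweep$durations)
  seq(0, total, by = sweep$sample_interval)
}

#' Sample times of every sweep in a protocol
#'
#' @param protocol a `clamp_protocol`
#' @return list of numeric vectors, one per sweep
#' @export
protocol_sample_times <- function(protocol) {
  lapply(protocol$sweeps, sweep_sample_times)
}

#' Per-sweep step voltages of a protocol
#'
#' For the standard three-segment sweeps this is the second (test) segment's
#' voltage; in general it is the voltage of the longest varying segment,
#' reported here simply as the second segment when present.
#'
#' @param protocol a `clamp_protocol`
#' @return numeric vector of voltages in mV
#' @export
protocol_step_voltages <- function(protocol) {
  vapply(protocol$sweeps, function(s) {
    if (length(s$voltages) >= 2L) s$voltages[[2L]] else s$voltages[[1L]]
  }, numeric(1))
}

#' Serialize a protocol to / from a plain list (YAML-friendly)
#'
#' The list layout is `sample_interval_ms` plus `sweeps`, each a list of
#' `{duration_ms, voltage_mV}` blocks.
#'
#' @param protocol a `clamp_protocol`
#' @return `protocol_to_list()`: a plain list; `protocol_from_list()`: a
#'   `clamp_protocol`.
#' @export
protocol_to_list <- function(protocol) {
  list(sample_interval_ms = protocol$sample_interval,
       sweeps = lapply(protocol$sweeps, function(s) {
         mapply(function(d, v) list(duration_ms = d, voltage_mV = v),
                s$durations, s$voltages, SIMPLIFY = FALSE)
       }))
}

#' @rdname protocol_to_list
#' @param x plain list as produced by `protocol_to_list()`
#' @export
protocol_from_list <- function(x) {
  si <- x$sample_interval_ms
  sweeps <- lapply(x$sweeps, function(sw) {
    sweep_protocol(lapply(sw, function(st) {
      voltage_step(st$duration_ms, st$voltage_mV)
    }), si)
  })
  clamp_protocol(sweeps)
}

#' @rdname protocol_to_list
#' @param path file path for the YAML rendering of the protocol
#' @export
write_protocol_yaml <- function(protocol, path) {
  yaml::write_yaml(protocol_to_list(protocol), path)
  invisible(path)
}

#' @rdname protocol_to_list
#' @export
read_protocol_yaml <- function(path) {
  protocol_from_list(yaml::read_yaml(path))
}
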