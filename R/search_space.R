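#' Box constraints for the adjustable parameters
#'
#' Maps the additive/multiplicative classification of a model's parameters to
#' the narrow or wide search space: additive parameters (voltage shifts, base
#' value b) vary in `[b - 60, b + 60]` (narrow) or `[b - 120, b + 120]`
#' (wide); multiplicative parameters vary between 0.1x and 10x (narrow) or
#' 0.01x and 100x (wide) of their base value, with the bounds sorted so that
#' lower < upper also for negative bases. Narrow intervals are strict subsets
#' of the wide ones and every base value lies strictly inside its interval.
#'
#' @param model a [current_model()]
#' @param width `"narrow"` or `"wide"`
#' @return an object of class `"search_space"`: a data frame with columns
#'   `name`, `base`, `role`, `lower`, `upper` and attributes `width` and
#'   `current_id`.
#' @export
make_bounds <- function(model, width = c("narrow", "wide")) {
  width <- match.arg(width)
  params <- model$params
  add <- if (width == "narrow") 60 else 120
  mul <- if (width == "narrow") c(0.1, 10) else c(0.01, 100)
  if (any(params$role == "multiplicative" & params$base == 0)) {
    stop("multiplicative parameters require a nonzero base value")
  }
  lo <- hi <- numeric(nrow(params))
  for (i in seq_len(nrow(params))) {
    b <- params$base[i]
    if (params$role[i] == "additive") {
      lo[i] <- b - add
      hi[i] <- b + add
    } else {
      bnds <- sort(mul * b)
      lo[i] <- bnds[1L]
      hi[i] <- bnds[2L]
    }
  }
  out <- data.frame(name = params$name, base = params$base,
                    role = params$role, lower = lo, upper = hi,
                    stringsAsFactors = FALSE)
  structure(out, width = width, current_id = model$current_id,
            class = c("search_space", "data.frame"))
}

space_lower <- function(space) space$lower
space_upper <- function(space) space$upper

#' Export a search space as a plain table
#'
#' @param space a [make_bounds()] result
#' @param path optional CSV path; when given the table is also written there
#' @return the table (invisibly when `path` is given)
#' @export
export_search_space <- function(space, path = NULL) {
  tab <- as.data.frame(space)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

# Precompile a protocol into the argument layout of the C++ simulator.
compile_protocol <- function(protocol) {
  totals <- vapply(protocol$sweeps, function(s) sum(s$durations), numeric(1))
  if (diff(range(totals)) > 1e-9) {
    stop("all sweeps must have equal total duration")
  }
  dt <- protocol$sample_interval
  list(seg_dur = lapply(protocol$sweeps, function(s) s$durations),
       seg_volt = lapply(protocol$sweeps, function(s) s$voltages),
       dt = dt, n_samples = length(sweep_sample_times(protocol$sweeps[[1L]])))
}

model_code <- function(model) {
  match(model$current_id, c("IKr", "IKur", "IKs"))
}

#' Least-squares objective over a multi-sweep trace
#'
#' Binds a current formulation, a clamp protocol, and an observed trace into
#' the sum-of-squared-errors objective minimized by all optimizers: residuals
#' are the sample-wise differences `I(t_i, V_j, p) - I*(t_i, V_j)`
#' concatenated over sweeps, and the cost is their squared Euclidean norm in
#' (pA/pF)^2. All samples of all sweeps enter the cost with unit weight.
#'
#' @param model a [current_model()]
#' @param protocol the [clamp_protocol()] the observations conform to
#' @param observed a [current_trace()] on the protocol's sample grid
#' @return an object of class `"clamp_objective"`
#' @export
build_objective <- function(model, protocol, observed) {
  comp <- compile_protocol(protocol)
  if (nrow(observed$current) != comp$n_samples ||
      ncol(observed$current) != length(protocol$sweeps)) {
    stop("observed trace does not conform to the protocol sample grid")
  }
  if (abs(observed$sample_interval - protocol$sample_interval) > 1e-9) {
    stop("observed trace sample interval differs from the protocol")
  }
  structure(list(model = model, protocol = protocol, observed = observed,
                 comp = comp, code = model_code(model),
                 n_residuals = comp$n_samples * length(protocol$sweeps)),
            class = "clamp_objective")
}

#' @export
print.clamp_objective <- function(x, ...) {
  cat(sprintf("objective: %s vs %s trace, %d residuals\n",
              x$model$current_id, x$observed$source, x$n_residuals))
  invisible(x)
}

#' Residual vector and cost of an objective
#'
#' @param obj a [build_objective()] result
#' @param p parameter vector
#' @return `residuals_at()`: numeric vector of residuals in pA/pF (errors if
#'   `p` is outside the model domain); `sse_cost()`: the sum of squared
#'   residuals in (pA/pF)^2, `+Inf` for parameter vectors producing invalid
#'   kinetics.
#' @export
residuals_at <- function(obj, p) {
  p <- check_par(obj$model, p)
  r <- cpp_residuals(obj$code, p, obj$comp$seg_dur, obj$comp$seg_volt,
                     obj$comp$dt, obj$model$E_K, obj$observed$current)
  if (length(r) == 0L) {
    stop(sprintf(
      "invalid %s parameter vector: non-positive or non-finite gate time constant at a protocol voltage",
      obj$model$current_id))
  }
  r
}

#' @rdname residuals_at
#' @export
sse_cost <- function(obj, p) {
  p <- check_par(obj$model, p)
  cpp_sse(obj$code, p, obj$comp$seg_dur, obj$comp$seg_volt,
          obj$comp$dt, obj$model$E_K, obj$observed$current)
}

# residual closure for the solvers; invalid vectors yield an error (TRR) --
# callers that want +Inf semantics use sse_cost.
objective_residual_fn <- function(obj) {
  function(p) residuals_at(obj, p)
}
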