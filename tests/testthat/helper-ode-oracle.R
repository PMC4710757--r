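# Independent numerical oracle: instead of the package's exact exponential
# gate updates, integrate the gating ODEs dx/dt = (x_inf(V) - x)/tau(V)
# segment by segment with deSolve::lsoda at tight tolerances and rebuild the
# current from the integrated gate values. Shares only the kinetics
# formulas with the package, not the propagation scheme, so agreement
# validates the analytic solution.
ode_simulate <- function(model, p = model$base,
                         protocol = standard_protocol()) {
  p <- as.numeric(p)
  gates <- clampfitr:::model_gates(model)
  cols <- lapply(protocol$sweeps, function(sweep) {
    ts <- seq(0, sum(sweep$durations), by = sweep$sample_interval)
    bounds <- cumsum(sweep$durations)
    starts <- c(0, bounds[-length(bounds)])
    state <- vapply(gates, function(g) {
      gate_steady_state(model, g, p, sweep$voltages[[1L]])
    }, numeric(1))
    names(state) <- gates
    out_gates <- matrix(NA_real_, length(ts), length(gates))
    out_v <- numeric(length(ts))
    for (s in seq_along(bounds)) {
      V <- sweep$voltages[[s]]
      kin <- lapply(gates, function(g) {
        clampfitr:::gate_kinetics(model, g, p, V)
      })
      names(kin) <- gates
      last <- s == length(bounds)
      idx <- which(ts >= starts[s] - 1e-9 &
                     (if (last) ts <= bounds[s] + 1e-9
                      else ts < bounds[s] - 1e-9))
      times <- sort(unique(round(c(starts[s], ts[idx], bounds[s]), 9)))
      rhs <- function(t, y, parms) {
        list(vapply(gates, function(g) {
          (kin[[g]]$inf - y[[g]]) / kin[[g]]$tau
        }, numeric(1)))
      }
      sol <- deSolve::lsoda(y = state, times = times, func = rhs,
                            rtol = 1e-11, atol = 1e-13)
      rows <- match(round(ts[idx], 9), round(sol[, "time"], 9))
      out_gates[idx, ] <- sol[rows, gates, drop = FALSE]
      out_v[idx] <- V
      state <- stats::setNames(as.numeric(sol[nrow(sol), gates]), gates)
    }
    gl <- stats::setNames(
      lapply(seq_along(gates), function(j) out_gates[, j]), gates)
    clampfitr:::current_from_gates(model, p, out_v, gl)
  })
  do.call(cbind, cols)
}
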