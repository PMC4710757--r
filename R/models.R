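#' Potassium Nernst voltage used by all current formulations
#'
#' Computed from the Nernst equation with the Courtemanche-standard
#' concentrations [K+]o = 5.4 mM and [K+]i = 139 mM at 310 K
#' (R = 8.3143 J/(mol K), F = 96.4867 C/mmol), giving -86.77 mV. E_K is a
#' fixed physical constant of the formulations and is never estimated.
#'
#' @return E_K in mV
#' @export
nernst_EK <- function() {
  (8.3143 * 310 / 96.4867) * log(5.4 / 139)
}

# Fixed (non-adjustable) model constants: temperature scaling of the I_Kur
# gate time constants and the I_Ks gate exponent.
KQ10 <- 3
XS_EXPONENT <- 2

model_param_table <- function(current_id) {
  df <- function(name, base, role) {
    data.frame(name = name, base = base, role = role,
               stringsAsFactors = FALSE)
  }
  switch(current_id,
    IKr = df(
      c("g_Kr", "inact_shift", "inact_slope",
        "xr_inf_shift", "xr_inf_slope",
        "alpha_xr_scale", "alpha_xr_shift_num", "alpha_xr_shift_exp",
        "alpha_xr_slope",
        "beta_xr_scale", "beta_xr_shift", "beta_xr_slope"),
      c(0.029411765, 15, 22.4,
        14.1, 6.5,
        0.0003, 14.1, 14.1, 5,
        7.3898e-5, 3.3328, 5.1237),
      c("multiplicative", "additive", "multiplicative",
        "additive", "multiplicative",
        "multiplicative", "additive", "additive", "multiplicative",
        "multiplicative", "additive", "multiplicative")),
    IKur = df(
      c("g_Kur_base", "g_Kur_amp", "g_Kur_shift", "g_Kur_slope",
        "ua_exponent",
        "alpha_ua_scale", "alpha_ua_shift1", "alpha_ua_slope1",
        "alpha_ua_shift2", "alpha_ua_slope2",
        "beta_ua_scale", "beta_ua_offset", "beta_ua_shift", "beta_ua_slope",
        "ua_inf_shift", "ua_inf_slope",
        "alpha_ui_scale", "alpha_ui_offset", "alpha_ui_shift",
        "alpha_ui_slope",
        "beta_ui_scale", "beta_ui_shift", "beta_ui_slope",
        "ui_inf_shift", "ui_inf_slope"),
      c(0.005, 0.05, 15, 13,
        3,
        0.65, 10, 8.5, 30, 59,
        0.65, 2.5, 82, 17,
        30.3, 9.6,
        1, 21, 185, 28,
        1, 158, 16,
        99.45, 27.48),
      c("multiplicative", "multiplicative", "additive", "multiplicative",
        "multiplicative",
        "multiplicative", "additive", "multiplicative",
        "additive", "multiplicative",
        "multiplicative", "multiplicative", "additive", "multiplicative",
        "additive", "multiplicative",
        "multiplicative", "multiplicative", "additive", "multiplicative",
        "multiplicative", "additive", "multiplicative",
        "additive", "multiplicative")),
    IKs = df(
      c("g_Ks",
        "alpha_xs_scale", "alpha_xs_shift_num", "alpha_xs_shift_exp",
        "alpha_xs_slope",
        "beta_xs_scale", "beta_xs_shift", "beta_xs_slope",
        "tau_xs_scale",
        "xs_inf_shift", "xs_inf_slope"),
      c(0.12941176,
        4e-5, 19.9, 19.9, 17,
        3.5e-5, 19.9, 9,
        0.5,
        19.9, 12.7),
      c("multiplicative",
        "multiplicative", "additive", "additive", "multiplicative",
        "multiplicative", "additive", "multiplicative",
        "multiplicative",
        "additive", "multiplicative")),
    stop("unknown current id: ", current_id))
}

#' Ion-current formulations of the Courtemanche human atrial model
#'
#' Builds the rapid (`IKr`), ultra-rapid (`IKur`), or slow (`IKs`) delayed
#' rectifier potassium current formulation with its ordered list of
#' adjustable parameters. Each parameter is classified as `additive` (a
#' voltage shift added to or subtracted from the transmembrane voltage, in
#' mV) or `multiplicative` (conductances in nS/pF, rate scales in 1/ms,
#' slopes in mV, dimensionless offsets and the I_Kur activation-gate
#' exponent); the classification drives the box-constraint construction in
#' [make_bounds()]. I_Kr exposes 12 adjustable parameters, I_Kur 25, and
#' I_Ks 11; the Q10 temperature factor of the I_Kur time constants and the
#' I_Ks gate exponent are fixed model constants, and E_K is never estimated.
#'
#' For I_Kr the voltage shift of the alpha_xr numerator and the shift inside
#' its exponential are independent parameters (both base 14.1 mV), whereas
#' the beta_xr shift is one parameter used in both its numerator and
#' exponential, which keeps that rate's singularity removable for every
#' admissible parameter vector; the same convention is used for the I_Ks
#' rates.
#'
#' @param current_id one of `"IKr"`, `"IKur"`, `"IKs"`
#' @return an object of class `"current_model"` with elements `current_id`,
#'   `params` (data frame: name, base, role), `base` (named base parameter
#'   vector), `n_params`, and `E_K`.
#' @export
current_model <- function(current_id = c("IKr", "IKur", "IKs")) {
  current_id <- match.arg(current_id)
  params <- model_param_table(current_id)
  base <- stats::setNames(params$base, params$name)
  structure(list(current_id = current_id, params = params, base = base,
                 n_params = nrow(params), E_K = nernst_EK()),
            class = "current_model")
}

#' @export
print.current_model <- function(x, ...) {
  cat(sprintf("%s formulation: %d adjustable parameters, E_K = %.2f mV\n",
              x$current_id, x$n_params, x$E_K))
  invisible(x)
}

check_par <- function(model, p) {
  if (length(p) != model$n_params) {
    stop(sprintf("parameter vector must have length %d for %s, got %d",
                 model$n_params, model$current_id, length(p)))
  }
  if (!all(is.finite(p))) stop("parameter vector must be finite")
  as.numeric(p)
}

# x / (1 - exp(-x / s)): removable singularity at x = 0 with limit s.
ratio_one_minus_exp <- function(x, s) {
  out <- x / (-expm1(-x / s))
  small <- abs(x) < 1e-7
  out[small] <- s + x[small] / 2
  out
}

# x / (exp(x / s) - 1): removable singularity at x = 0 with limit s.
ratio_expm1 <- function(x, s) {
  out <- x / expm1(x / s)
  small <- abs(x) < 1e-7
  out[small] <- s - x[small] / 2
  out
}

# Voltage-shifted rate of the form scale * (V + a) / (1 - exp(-(V + b)/s)).
# When a == b the singularity at V = -b is removable (limit scale * s); when
# the two shifts have drifted apart during a fit the expression has a true
# pole there and the raw ratio is returned (downstream validity checks on
# the time constant reject such vectors).
rate_alpha_form <- function(V, scale, a, b, s) {
  u <- V + b
  if (abs(a - b) < 1e-9) {
    scale * ratio_one_minus_exp(u, s)
  } else {
    scale * (V + a) / (-expm1(-u / s))
  }
}

# Gate kinetics: steady state and time constant per gate at one voltage.
# Returns list(inf, tau). V may be a vector.
gate_kinetics <- function(model, gate, p, V) {
  id <- model$current_id
  if (id == "IKr" && gate == "xr") {
    a <- rate_alpha_form(V, p[6], p[7], p[8], p[9])
    b <- p[10] * ratio_expm1(V - p[11], p[12])
    return(list(inf = 1 / (1 + exp(-(V + p[4]) / p[5])), tau = 1 / (a + b)))
  }
  if (id == "IKur" && gate == "ua") {
    a <- p[6] / (exp(-(V + p[7]) / p[8]) + exp(-(V - p[9]) / p[10]))
    b <- p[11] / (p[12] + exp((V + p[13]) / p[14]))
    return(list(inf = 1 / (1 + exp(-(V + p[15]) / p[16])),
                tau = 1 / ((a + b) * KQ10)))
  }
  if (id == "IKur" && gate == "ui") {
    a <- p[17] / (p[18] + exp(-(V - p[19]) / p[20]))
    b <- p[21] * exp((V - p[22]) / p[23])
    return(list(inf = 1 / (1 + exp((V - p[24]) / p[25])),
                tau = 1 / ((a + b) * KQ10)))
  }
  if (id == "IKs" && gate == "xs") {
    a <- rate_alpha_form(V, p[2], -p[3], -p[4], p[5])
    b <- p[6] * ratio_expm1(V - p[7], p[8])
    return(list(inf = (1 + exp(-(V - p[10]) / p[11]))^(-0.5),
                tau = p[9] / (a + b)))
  }
  stop(sprintf("unknown gate '%s' for current %s", gate, id))
}

model_gates <- function(model) {
  switch(model$current_id, IKr = "xr", IKur = c("ua", "ui"), IKs = "xs")
}

#' Gate steady state and time constant
#'
#' Voltage-dependent steady-state open fraction and relaxation time constant
#' of a Hodgkin-Huxley gating variable. Gates: `"xr"` (I_Kr), `"ua"`/`"ui"`
#' (I_Kur activation/inactivation), `"xs"` (I_Ks).
#'
#' @param model a [current_model()]
#' @param gate gate identifier
#' @param p parameter vector (defaults to the model's base values)
#' @param Vm transmembrane voltage in mV (vectorized)
#' @return `gate_steady_state()`: dimensionless fraction in (0, 1);
#'   `gate_time_constant()`: time constant in ms.
#' @export
gate_steady_state <- function(model, gate, p = model$base, Vm) {
  p <- check_par(model, p)
  gate_kinetics(model, gate, p, Vm)$inf
}

#' @rdname gate_steady_state
#' @export
gate_time_constant <- function(model, gate, p = model$base, Vm) {
  p <- check_par(model, p)
  gate_kinetics(model, gate, p, Vm)$tau
}

#' I_Kr activation rate constants
#'
#' The opening rate alpha_xr(V) = p6 (V + p7) / (1 - exp(-(V + p8)/p9)) and
#' closing rate beta_xr(V) = p10 (V - p11) / (exp((V - p11)/p12) - 1), both
#' in 1/ms. At the removable singularities the analytic series limits are
#' returned (alpha: p6 * p9 = 0.0015 1/ms at V = -14.1 mV with base values).
#'
#' @param p I_Kr parameter vector (defaults to base values)
#' @param Vm voltage in mV (vectorized)
#' @return rate in 1/ms
#' @export
gate_rate_alpha_xr <- function(p = current_model("IKr")$base, Vm) {
  p <- check_par(current_model("IKr"), p)
  rate_alpha_form(Vm, p[6], p[7], p[8], p[9])
}

#' @rdname gate_rate_alpha_xr
#' @export
gate_rate_beta_xr <- function(p = current_model("IKr")$base, Vm) {
  p <- check_par(current_model("IKr"), p)
  p[10] * ratio_expm1(Vm - p[11], p[12])
}

#' Analytic exponential gate update
#'
#' Exact solution of dx/dt = (x_inf - x)/tau over a constant-voltage segment:
#' `x(dt) = x_inf + (x0 - x_inf) exp(-dt/tau)`.
#'
#' @param x0 initial gate value
#' @param x_inf steady-state value for the segment
#' @param tau time constant in ms (> 0)
#' @param dt elapsed time in ms (>= 0, vectorized)
#' @return gate value(s) between `x0` and `x_inf`
#' @export
gate_update <- function(x0, x_inf, tau, dt) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive and finite")
  stopifnot(all(dt >= 0))
  x_inf + (x0 - x_inf) * exp(-dt / tau)
}

# Instantaneous current from gate values at sampled voltages.
current_from_gates <- function(model, p, V, gates) {
  EK <- model$E_K
  switch(model$current_id,
    IKr = p[1] * gates$xr * (V - EK) / (1 + exp((V + p[2]) / p[3])),
    IKur = (p[1] + p[2] / (1 + exp(-(V - p[3]) / p[4]))) *
      gates$ua^p[5] * gates$ui * (V - EK),
    IKs = p[1] * gates$xs^XS_EXPONENT * (V - EK))
}

#' Piecewise-analytic voltage-clamp simulation
#'
#' Simulates the current density elicited by a multi-sweep step protocol.
#' Because the command voltage is piecewise constant, every gating variable
#' relaxes exponentially within each segment and the gating ODEs are solved
#' exactly segment by segment ([gate_update()]); no numerical ODE integration
#' is involved. Gates are initialized at the steady state of each sweep's
#' first segment voltage (the holding potential).
#'
#' @param model a [current_model()]
#' @param p parameter vector (defaults to the model's base values)
#' @param protocol a [clamp_protocol()]
#' @return a [current_trace()] with one current column per sweep (pA/pF)
#' @export
simulate_current <- function(model, p = model$base,
                             protocol = standard_protocol()) {
  p <- check_par(model, p)
  comp <- compile_protocol(protocol)
  cur <- cpp_simulate(model_code(model), p, comp$seg_dur, comp$seg_volt,
                      comp$dt, model$E_K, comp$n_samples)
  if (isTRUE(attr(cur, "invalid"))) {
    stop(sprintf(
      "invalid %s parameter vector: non-positive or non-finite gate time constant at a protocol voltage",
      model$current_id))
  }
  attr(cur, "invalid") <- NULL
  current_trace(time = sweep_sample_times(protocol$sweeps[[1L]]),
                current = cur,
                step_voltages = protocol_step_voltages(protocol),
                sample_interval = protocol$sample_interval,
                source = "synthetic", model_id = model$current_id)
}

# Pure-R reference simulation; same semantics as simulate_current() but
# evaluated with scalar gate updates. Used to cross-check the compiled path.
simulate_current_r <- function(model, p = model$base,
                               protocol = standard_protocol()) {
  p <- check_par(model, p)
  gates <- model_gates(model)
  cols <- lapply(protocol$sweeps, function(sweep) {
    ts <- sweep_sample_times(sweep)
    simulate_sweep_r(model, p, sweep, ts, gates)
  })
  n <- vapply(cols, length, integer(1))
  if (length(unique(n)) != 1L) {
    stop("sweeps of unequal duration are not supported in a single trace")
  }
  current_trace(time = sweep_sample_times(protocol$sweeps[[1L]]),
                current = do.call(cbind, cols),
                step_voltages = protocol_step_voltages(protocol),
                sample_interval = protocol$sample_interval,
                source = "synthetic", model_id = model$current_id)
}

simulate_sweep_r <- function(model, p, sweep, ts, gates) {
  bounds <- cumsum(sweep$durations)
  starts <- c(0, bounds[-length(bounds)])
  total <- bounds[length(bounds)]
  # per-gate state initialized at the holding-potential steady state
  kin0 <- lapply(gates, function(g) gate_kinetics(model, g, p, sweep$voltages[1L]))
  x0 <- vapply(kin0, function(k) k$inf, numeric(1))
  out <- numeric(length(ts))
  for (s in seq_along(sweep$durations)) {
    V <- sweep$voltages[[s]]
    kin <- lapply(gates, function(g) gate_kinetics(model, g, p, V))
    tau <- vapply(kin, function(k) k$tau, numeric(1))
    inf <- vapply(kin, function(k) k$inf, numeric(1))
    if (any(!is.finite(tau)) || any(tau <= 0)) {
      bad <- gates[!is.finite(tau) | tau <= 0]
      stop(sprintf(
        "invalid parameters: non-positive or non-finite time constant for gate '%s' at V = %g mV",
        paste(bad, collapse = ","), V))
    }
    last <- s == length(sweep$durations)
    idx <- which(ts >= starts[s] - 1e-9 &
                   (if (last) ts <= bounds[s] + 1e-9 else ts < bounds[s] - 1e-9))
    if (length(idx)) {
      dtl <- ts[idx] - starts[s]
      gvals <- stats::setNames(lapply(seq_along(gates), function(k) {
        gate_update(x0[k], inf[k], tau[k], dtl)
      }), gates)
      out[idx] <- current_from_gates(model, p, V, gvals)
    }
    x0 <- vapply(seq_along(gates), function(k) {
      gate_update(x0[k], inf[k], tau[k], sweep$durations[[s]])
    }, numeric(1))
  }
  out
}
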