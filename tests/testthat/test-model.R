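test_that("the potassium Nernst voltage is -86.77 mV", {
  expect_equal(nernst_EK(), (8.3143 * 310 / 96.4867) * log(5.4 / 139))
  expect_equal(round(nernst_EK(), 2), -86.77)
})

test_that("adjustable parameter counts are 12 (IKr), 25 (IKur), 11 (IKs)", {
  expect_equal(fix_model("IKr")$n_params, 12L)
  expect_equal(fix_model("IKur")$n_params, 25L)
  expect_equal(fix_model("IKs")$n_params, 11L)
  for (id in c("IKr", "IKur", "IKs")) {
    m <- fix_model(id)
    expect_named(m$base, m$params$name)
    expect_true(all(m$params$role %in% c("additive", "multiplicative")))
  }
})

test_that("gate_update is the exact exponential relaxation", {
  expect_equal(gate_update(0.2, 0.8, 10, 10), 0.8 - 0.6 * exp(-1))
  expect_equal(gate_update(0.5, 0.5, 3, 100), 0.5)
  expect_equal(gate_update(0.9, 0.1, 5, 0), 0.9)
  # monotone approach, always between x0 and x_inf
  dts <- seq(0, 50, by = 1)
  xs <- gate_update(0.1, 0.7, 8, dts)
  expect_true(all(diff(xs) > 0))
  expect_true(all(xs >= 0.1 - 1e-12 & xs <= 0.7 + 1e-12))
  expect_error(gate_update(0.2, 0.8, -1, 10), "tau")
})

test_that("steady states lie in (0, 1) and time constants are positive", {
  V <- seq(-120, 60, by = 1)
  for (id in c("IKr", "IKur", "IKs")) {
    m <- fix_model(id)
    for (g in clampfitr:::model_gates(m)) {
      inf <- gate_steady_state(m, g, Vm = V)
      tau <- gate_time_constant(m, g, Vm = V)
      expect_true(all(inf > 0 & inf < 1), info = paste(id, g))
      expect_true(all(is.finite(tau) & tau > 0), info = paste(id, g))
    }
  }
})

test_that("the IKr activation rates take their series limits at the poles", {
  # alpha_xr: removable singularity at V = -14.1 with limit scale * slope
  expect_equal(gate_rate_alpha_xr(Vm = -14.1), 0.0003 * 5)
  # continuity across the singular point
  near <- gate_rate_alpha_xr(Vm = -14.1 + c(-1e-6, 1e-6))
  expect_true(all(abs(near - 0.0015) < 1e-9))
  # beta_xr: removable singularity at V = 3.3328 with limit scale * slope
  expect_equal(gate_rate_beta_xr(Vm = 3.3328), 7.3898e-5 * 5.1237)
  expect_true(all(is.finite(gate_rate_beta_xr(Vm = seq(-100, 60, by = 0.1)))))
})

test_that("IKur time constants carry the fixed Q10 division by 3", {
  m <- fix_model("IKur")
  p <- m$base
  V <- 0
  a <- p[["alpha_ua_scale"]] /
    (exp(-(V + p[["alpha_ua_shift1"]]) / p[["alpha_ua_slope1"]]) +
       exp(-(V - p[["alpha_ua_shift2"]]) / p[["alpha_ua_slope2"]]))
  b <- p[["beta_ua_scale"]] /
    (p[["beta_ua_offset"]] + exp((V + p[["beta_ua_shift"]]) /
                                   p[["beta_ua_slope"]]))
  expect_equal(gate_time_constant(m, "ua", Vm = V), 1 / (3 * (a + b)))
})

test_that("simulated current starts at the holding-potential steady state", {
  for (id in c("IKr", "IKur", "IKs")) {
    m <- fix_model(id)
    tr <- fix_truth(id)
    gates <- clampfitr:::model_gates(m)
    gl <- stats::setNames(lapply(gates, function(g) {
      gate_steady_state(m, g, Vm = -80)
    }), gates)
    i0 <- unname(clampfitr:::current_from_gates(m, m$base, -80, gl))
    expect_equal(unname(tr$current[1, ]), rep(i0, 13), tolerance = 1e-12,
                 info = id)
  }
})

test_that("splitting a constant-voltage segment does not change the trace", {
  m <- fix_model("IKr")
  whole <- clamp_protocol(list(sweep_protocol(
    list(voltage_step(20, -80), voltage_step(400, 20),
         voltage_step(400, -110)), 2)))
  split <- clamp_protocol(list(sweep_protocol(
    list(voltage_step(20, -80), voltage_step(150, 20), voltage_step(250, 20),
         voltage_step(100, -110), voltage_step(300, -110)), 2)))
  a <- simulate_current(m, m$base, whole)
  b <- simulate_current(m, m$base, split)
  expect_equal(a$current, b$current, tolerance = 1e-12)
})

test_that("parameter vectors of the wrong length or with NAs are rejected", {
  m <- fix_model("IKr")
  expect_error(simulate_current(m, m$base[-1]), "length 12")
  bad <- m$base
  bad[3] <- NA
  expect_error(simulate_current(m, bad), "finite")
})

test_that("compiled and reference simulators agree on random vectors", {
  proto <- fix_protocol()
  for (id in c("IKr", "IKur", "IKs")) {
    m <- fix_model(id)
    obj <- fix_objective(id)
    space <- make_bounds(m, "narrow")
    set.seed(2024)
    for (k in 1:5) {
      p <- draw_valid_start(obj, space)
      r_trace <- clampfitr:::simulate_current_r(m, p, proto)
      res <- residuals_at(obj, p)
      ref <- as.numeric(r_trace$current - fix_truth(id)$current)
      expect_equal(res, ref, tolerance = 1e-10, info = paste(id, k))
    }
  }
})
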