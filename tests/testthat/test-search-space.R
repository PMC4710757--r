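test_that("additive bounds are base +/- 60 (narrow) and +/- 120 (wide)", {
  for (id in c("IKr", "IKur", "IKs")) {
    m <- fix_model(id)
    nar <- make_bounds(m, "narrow")
    wid <- make_bounds(m, "wide")
    a <- nar$role == "additive"
    expect_equal(nar$lower[a], nar$base[a] - 60)
    expect_equal(nar$upper[a], nar$base[a] + 60)
    expect_equal(wid$lower[a], wid$base[a] - 120)
    expect_equal(wid$upper[a], wid$base[a] + 120)
  }
})

test_that("multiplicative bounds span 0.1-10x (narrow) and 0.01-100x (wide)", {
  m <- fix_model("IKur")
  nar <- make_bounds(m, "narrow")
  wid <- make_bounds(m, "wide")
  mm <- nar$role == "multiplicative"
  expect_equal(nar$lower[mm], pmin(0.1 * nar$base[mm], 10 * nar$base[mm]))
  expect_equal(nar$upper[mm], pmax(0.1 * nar$base[mm], 10 * nar$base[mm]))
  expect_equal(wid$lower[mm], pmin(0.01 * wid$base[mm], 100 * wid$base[mm]))
  expect_equal(wid$upper[mm], pmax(0.01 * wid$base[mm], 100 * wid$base[mm]))
})

test_that("narrow spaces nest strictly inside wide spaces around the base", {
  for (id in c("IKr", "IKur", "IKs")) {
    m <- fix_model(id)
    nar <- make_bounds(m, "narrow")
    wid <- make_bounds(m, "wide")
    expect_true(all(nar$lower < nar$upper), info = id)
    expect_true(all(wid$lower <= nar$lower), info = id)
    expect_true(all(nar$upper <= wid$upper), info = id)
    expect_true(all(nar$lower < nar$base & nar$base < nar$upper), info = id)
  }
})

test_that("objectives have one residual per sample and a zero cost floor", {
  for (id in c("IKr", "IKur", "IKs")) {
    m <- fix_model(id)
    obj <- fix_objective(id)
    expect_equal(obj$n_residuals, 13L * 411L)
    r <- residuals_at(obj, m$base)
    expect_length(r, 5343L)
    expect_true(all(r == 0), info = id)
    expect_identical(sse_cost(obj, m$base), 0)
  }
})

test_that("the cost is the squared Euclidean norm of the residuals", {
  obj <- fix_objective("IKr")
  space <- make_bounds(fix_model("IKr"), "narrow")
  set.seed(11)
  p <- draw_valid_start(obj, space)
  expect_equal(sse_cost(obj, p), sum(residuals_at(obj, p)^2),
               tolerance = 1e-12)
})

test_that("kinetically invalid vectors cost +Inf and refuse residuals", {
  # pulling the two alpha_xr shifts far apart leaves a true pole of the
  # activation rate inside the protocol's voltage range
  m <- fix_model("IKr")
  obj <- fix_objective("IKr")
  bad <- m$base
  bad[["alpha_xr_shift_num"]] <- 74.1
  bad[["alpha_xr_shift_exp"]] <- -45.9
  expect_identical(sse_cost(obj, bad), Inf)
  expect_error(residuals_at(obj, bad), "invalid")
})

test_that("objectives reject traces on a different sample grid", {
  m <- fix_model("IKr")
  proto <- fix_protocol()
  short <- clamp_protocol(list(sweep_protocol(
    list(voltage_step(20, -80), voltage_step(100, 20)), 2)))
  tr_short <- simulate_current(m, m$base, short)
  expect_error(build_objective(m, proto, tr_short), "grid")
})

test_that("export_search_space writes a readable CSV", {
  space <- make_bounds(fix_model("IKr"), "wide")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  export_search_space(space, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$name, space$name)
  expect_equal(back$lower, space$lower)
  expect_equal(back$upper, space$upper)
})
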