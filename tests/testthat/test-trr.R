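test_that("a linear least-squares problem is solved to machine precision", {
  # residuals A p - b with known solution (1, 2)
  A <- matrix(c(2, 0, 1, 0, 3, 1), 3, 2)
  b <- A %*% c(1, 2)
  res_fn <- function(p) drop(A %*% p - b)
  fit <- trr_minimize(res_fn, c(-3, 4), toy_space())
  expect_equal(fit$par, c(1, 2), tolerance = 1e-7)
  expect_lt(fit$cost, 1e-16)
})

test_that("the Rosenbrock valley is traversed to the global minimum", {
  res_fn <- function(p) c(10 * (p[2] - p[1]^2), 1 - p[1])
  fit <- trr_minimize(res_fn, c(-1.2, 1), toy_space())
  expect_equal(fit$par, c(1, 1), tolerance = 1e-6)
  expect_lt(fit$cost, 1e-15)
})

test_that("a constrained optimum lands on its active bound", {
  res_fn <- function(p) p - c(7, -1)  # unconstrained optimum outside the box
  fit <- trr_minimize(res_fn, c(0, 0), toy_space(c(-5, -5), c(5, 5)))
  # the active bound pins the cost at 4, so the absolute fTol = 1e-11
  # stopping rule leaves a residual parameter error of order sqrt(fTol)
  expect_equal(fit$par[1], 5, tolerance = 1e-4)
  expect_equal(fit$par[2], -1, tolerance = 1e-4)
})

test_that("iterates stay within bounds and descend monotonically", {
  obj <- fix_objective("IKr")
  space <- make_bounds(fix_model("IKr"), "narrow")
  res_fn <- clampfitr:::objective_residual_fn(obj)
  set.seed(301)
  p0 <- draw_valid_start(obj, space)
  fit <- trr_minimize(res_fn, p0, space, trr_control(max_iter = 200))
  expect_true(all(fit$par >= space$lower & fit$par <= space$upper))
  expect_true(all(diff(fit$trace) <= 0))
  expect_lte(fit$cost, sse_cost(obj, p0))
  expect_true(fit$termination %in%
                c("pTol", "fTol", "maxIter", "maxFunEval"))
})

test_that("rank-deficient Jacobians do not break the subproblem solver", {
  # two exactly redundant residual components plus an independent one give
  # a Jacobian with an exactly zero singular value
  res_fn <- function(p) c(p[1] + p[2] - 1, p[1] + p[2] - 1, 5 * (p[3] + 2))
  fit <- trr_minimize(res_fn, c(3, -4, 4.5), toy_space(rep(-5, 3), rep(5, 3)))
  expect_lt(fit$cost, 1e-14)
  expect_equal(fit$par[1] + fit$par[2], 1, tolerance = 1e-6)
  expect_equal(fit$par[3], -2, tolerance = 1e-6)
})

test_that("iteration caps and budgets are honored and reported", {
  res_fn <- function(p) c(10 * (p[2] - p[1]^2), 1 - p[1])
  capped <- trr_step_limited(res_fn, c(-1.2, 1), toy_space(), K = 3)
  expect_lte(capped$iterations, 3L)
  expect_equal(capped$termination, "iteration_cap")
  full <- trr_minimize(res_fn, c(-1.2, 1), toy_space())
  expect_lte(full$cost, capped$cost)
  starved <- trr_minimize(res_fn, c(-1.2, 1), toy_space(),
                          trr_control(max_fev = 12))
  expect_equal(starved$termination, "maxFunEval")
})

test_that("more embedded iterations never increase the capped cost", {
  obj <- fix_objective("IKr")
  space <- make_bounds(fix_model("IKr"), "narrow")
  res_fn <- clampfitr:::objective_residual_fn(obj)
  set.seed(77)
  p0 <- draw_valid_start(obj, space)
  c1 <- trr_step_limited(res_fn, p0, space, K = 1)$cost
  c5 <- trr_step_limited(res_fn, p0, space, K = 5)$cost
  c0 <- sse_cost(obj, p0)
  expect_lte(c1, c0)
  expect_lte(c5, c1)
})

test_that("invalid starts are rejected with clear errors", {
  res_fn <- function(p) p
  expect_error(trr_minimize(res_fn, c(9, 0), toy_space()), "outside")
  bad_fn <- function(p) c(NaN, 1)
  expect_error(trr_minimize(bad_fn, c(0, 0), toy_space()), "finite")
  expect_error(trr_control(ftol = -1))
})
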