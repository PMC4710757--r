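test_that("hybrid setups expose the published budget tiers plus desk", {
  low <- hybrid_setup("low")
  expect_equal(low[c("K", "L", "N", "M")], list(K = 5, L = 250, N = 96,
                                                M = 12))
  med <- hybrid_setup("medium")
  expect_equal(med[c("K", "L", "N", "M")], list(K = 10, L = 500, N = 192,
                                                M = 12))
  high <- hybrid_setup("high")
  expect_equal(high[c("K", "L", "N", "M")], list(K = 20, L = 1000, N = 384,
                                                 M = 12))
  desk <- hybrid_setup("desk")
  expect_equal(desk[c("K", "L", "N", "M")], list(K = 5, L = 60, N = 48,
                                                 M = 8))
  expect_equal(hybrid_setup("desk", M = 4)$M, 4)
  expect_error(hybrid_setup("desk", M = 100))
})

test_that("with K = 0 the engine reproduces pure PSO draw for draw", {
  obj <- fix_objective("IKr")
  space <- make_bounds(fix_model("IKr"), "wide")
  a <- pso_run(obj, space, pso_config(N = 8, L = 5, seed = 42))
  b <- clampfitr:::swarm_engine(obj, space, N = 8, L = 5, K = 0, M = 0,
                                seed = 42)
  expect_identical(a$best_par, b$best_par)
  expect_identical(a$convergence, b$convergence)
  expect_identical(a$personal_best_costs, b$personal_best_costs)
})

test_that("embedded refinement accelerates the swarm on a toy problem", {
  obj <- toy_objective()
  space <- toy_space()
  plain <- clampfitr:::swarm_engine(obj, space, N = 6, L = 10, K = 0,
                                    M = 0, seed = 5)
  hyb <- clampfitr:::swarm_engine(obj, space, N = 6, L = 10, K = 3,
                                  M = 0, seed = 5)
  expect_lte(hyb$best_cost, plain$best_cost)
  expect_lt(hyb$best_cost, 1e-12)
  expect_true(all(diff(hyb$convergence$best) <= 0))
})

test_that("hybrid runs are seed-reproducible and respect bounds", {
  obj <- toy_objective()
  setup <- hybrid_setup("desk", M = 2)
  setup$N <- 6; setup$L <- 8
  a <- hybrid_run(obj, toy_space(), setup, seed = 11)
  b <- hybrid_run(obj, toy_space(), setup, seed = 11)
  expect_identical(a$best_par, b$best_par)
  expect_identical(a$best_cost, b$best_cost)
  expect_true(all(a$best_par >= toy_space()$lower &
                    a$best_par <= toy_space()$upper))
})

test_that("the terminal refinement stage never increases the best cost", {
  obj <- toy_objective()
  setup <- hybrid_setup("desk", M = 3)
  setup$N <- 6; setup$L <- 5
  with_ref <- hybrid_run(obj, toy_space(), setup, seed = 2)
  expect_lte(with_ref$best_cost, with_ref$pre_refine_cost)
  expect_equal(nrow(with_ref$refinement$table), 3L)
  expect_true(all(with_ref$refinement$table$cost <=
                    with_ref$refinement$table$pre_cost))
  no_ref <- hybrid_run(obj, toy_space(), setup, seed = 2,
                       final_refine = FALSE)
  expect_null(no_ref$refinement)
  expect_identical(no_ref$best_cost, no_ref$pre_refine_cost)
})

test_that("two-stage estimation refines the swarm's ranked personal bests", {
  obj <- fix_objective("IKr")
  space <- make_bounds(fix_model("IKr"), "narrow")
  swarm <- pso_run(obj, space, pso_config(N = 8, L = 15, seed = 6))
  two <- two_stage_run(obj, space, N = 8, L = 15, M = 3, seed = 6)
  expect_lte(two$best_cost, swarm$best_cost)
  expect_equal(two$config$algorithm, "two_stage")
  expect_lte(nrow(two$refinement$table), 3L)
})

test_that("final_refine reports the relative improvement over the input", {
  obj <- toy_objective()
  ranked <- rbind(c(2, 0), c(0, 0))
  out <- final_refine(obj, ranked, toy_space(), M = 2)
  expect_lt(out$best_cost, 1e-14)
  expect_equal(out$delta_rel, 1, tolerance = 1e-10)
  expect_equal(nrow(out$table), 2L)
})
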