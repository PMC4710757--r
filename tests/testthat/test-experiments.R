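test_that("experiment plans validate their data requirements", {
  expect_error(experiment_plan("IKr", "trr", "narrow", "noisy"), "snr_db")
  expect_error(experiment_plan("IKr", "trr", "narrow", "file"), "path")
  plan <- experiment_plan("IKr", "pso", "narrow", n_runs = 3, seed = 7,
                          config = list(N = 4, L = 5))
  expect_s3_class(plan, "experiment_plan")
  expect_equal(plan$n_runs, 3L)
})

test_that("distribution summaries are consistent order statistics", {
  s <- distribution_summary(c(5, 1, 3, 2, 4))
  expect_equal(unname(s[c("min", "median", "max")]), c(1, 3, 5))
  expect_true(all(diff(s) >= 0))
  one <- distribution_summary(4.2)
  expect_true(all(one == 4.2))
})

test_that("a TRR experiment produces per-run records and a summary", {
  plan <- experiment_plan("IKr", "trr", "narrow", n_runs = 3, seed = 30,
                          config = list(control = trr_control(max_iter = 40)))
  res <- run_experiment(plan)
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$runs), 3L)
  expect_true(all(is.finite(res$runs$cost)))
  expect_true(all(res$runs$gt_sse >= 0))
  expect_equal(res$summary[["min"]], min(res$runs$cost))
  expect_equal(ncol(res$params), 12L)
  expect_equal(res$ground_truth, fix_model("IKr")$base)
  expect_true(all(res$runs$termination %in%
                    c("pTol", "fTol", "maxIter", "maxFunEval")))
})

test_that("experiments are reproducible from the master seed", {
  plan <- experiment_plan("IKr", "pso", "narrow", n_runs = 2, seed = 12,
                          config = list(N = 5, L = 8))
  a <- run_experiment(plan)
  b <- run_experiment(plan)
  expect_identical(a$runs$cost, b$runs$cost)
  expect_identical(a$params, b$params)
})

test_that("run records persist as JSON lines plus a CSV summary", {
  dir <- tempfile("exp")
  on.exit(unlink(dir, recursive = TRUE))
  plan <- experiment_plan("IKr", "pso", "narrow", n_runs = 2, seed = 3,
                          config = list(N = 4, L = 5))
  run_experiment(plan, dir = dir)
  jsonl <- file.path(dir, "IKr_pso_narrow_clean_seed3.jsonl")
  expect_true(file.exists(jsonl))
  lines <- readLines(jsonl)
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_length(rec$par, 12L)
  expect_true(is.finite(rec$cost))
  expect_true(file.exists(file.path(dir,
                                    "IKr_pso_narrow_clean_seed3_summary.csv")))
})

test_that("the noise study reports both error metrics and the noise floor", {
  tab <- noise_study("IKr", snr_db = 20, include_clean = TRUE,
                     algorithms = "trr", width = "narrow", n_runs = 2,
                     seed = 8,
                     config = list(control = trr_control(max_iter = 30)))
  expect_equal(nrow(tab), 2L)
  clean_row <- tab[is.na(tab$snr_db), ]
  noisy_row <- tab[!is.na(tab$snr_db), ]
  expect_equal(clean_row$noise_energy, 0)
  expect_gt(noisy_row$noise_energy, 0)
  # vs-input cost cannot undercut the injected noise energy by much more
  # than the fitting error; allow slack for non-converged short runs
  expect_true(is.finite(noisy_row$median_cost_vs_input))
  expect_true(is.finite(noisy_row$median_sse_vs_ground_truth))
})

test_that("the particle sweep fits a regression of median cost on log2(N)", {
  out <- sweep_particles("pso", N_list = c(4, 8), current = "IKr",
                         width = "narrow", n_runs = 2, L = 10, seed = 5)
  expect_equal(out$table$N, c(4, 8))
  expect_true(all(is.finite(out$table$median)))
  expect_s3_class(out$regression, "lm")
  expect_length(stats::coef(out$regression), 2L)
})

test_that("reporting writes the summary table and figures", {
  dir <- tempfile("report")
  on.exit(unlink(dir, recursive = TRUE))
  plan <- experiment_plan("IKr", "pso", "narrow", n_runs = 2, seed = 4,
                          config = list(N = 4, L = 6))
  res <- run_experiment(plan)
  tab <- report_experiments(list(res), dir)
  expect_true(file.exists(file.path(dir, "summaries.csv")))
  expect_true(file.exists(file.path(dir, "cost_boxplots.pdf")))
  expect_equal(nrow(tab), 1L)
  # convergence plot from the raw swarm runs
  obj <- fix_objective("IKr")
  space <- make_bounds(fix_model("IKr"), "narrow")
  run <- pso_run(obj, space, pso_config(N = 4, L = 6, seed = 1))
  pdf_path <- file.path(dir, "convergence.pdf")
  stats_df <- plot_convergence(run, pdf_path)
  expect_true(file.exists(pdf_path))
  expect_equal(nrow(stats_df), 7L)
})
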