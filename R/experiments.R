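#' Experiment plan: repeated seeded estimation runs
#'
#' Describes one experimental cell: which current, which data source (clean
#' synthetic, noisy synthetic at a given SNR, or a trace file), which
#' algorithm and configuration, which search-space width, and how many
#' repetitions. Every repetition receives a distinct derived seed
#' (`seed + run index`).
#'
#' @param current `"IKr"`, `"IKur"`, or `"IKs"`
#' @param algorithm `"trr"`, `"pso"`, `"two_stage"`, or `"hybrid"`
#' @param width `"narrow"` or `"wide"`
#' @param data `"clean"`, `"noisy"`, or `"file"`
#' @param snr_db SNR in dB when `data = "noisy"`
#' @param file trace CSV path when `data = "file"`
#' @param n_runs number of repetitions (default 25)
#' @param seed master seed
#' @param config algorithm configuration overrides: `N`, `L`, `M` for the
#'   swarm algorithms, `setup` (a [hybrid_setup()] or its name) for the
#'   hybrid, `control` (a [trr_control()]) for TRR stages
#' @return list of class `"experiment_plan"`
#' @export
experiment_plan <- function(current = c("IKr", "IKur", "IKs"),
                            algorithm = c("trr", "pso", "two_stage",
                                          "hybrid"),
                            width = c("narrow", "wide"),
                            data = c("clean", "noisy", "file"),
                            snr_db = NULL, file = NULL, n_runs = 25,
                            seed = 1L, config = list()) {
  current <- match.arg(current)
  algorithm <- match.arg(algorithm)
  width <- match.arg(width)
  data <- match.arg(data)
  stopifnot(n_runs >= 1)
  if (data == "noisy" && is.null(snr_db)) stop("noisy data needs snr_db")
  if (data == "file" && is.null(file)) stop("file data needs a path")
  structure(list(current = current, algorithm = algorithm, width = width,
                 data = data, snr_db = snr_db, file = file,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 config = config),
            class = "experiment_plan")
}

#' Order-statistic summary of final costs
#'
#' @param costs numeric vector of per-run final costs
#' @return named vector: min, q1, median, q3, max
#' @export
distribution_summary <- function(costs) {
  stats::setNames(stats::quantile(costs, c(0, .25, .5, .75, 1),
                                  names = FALSE),
                  c("min", "q1", "median", "q3", "max"))
}

# uniform random start within the space; redrawn until the objective is
# finite there (wide spaces contain kinetically invalid vectors)
random_start <- function(objective, space, max_tries = 200) {
  bb <- space_bounds(space)
  for (k in seq_len(max_tries)) {
    p <- stats::runif(length(bb$lower), bb$lower, bb$upper)
    if (is.finite(safe_cost(objective, p))) return(p)
  }
  stop("could not draw a feasible start vector")
}

plan_objective <- function(plan, protocol) {
  model <- current_model(plan$current)
  clean <- generate_ground_truth(model, protocol)
  observed <- switch(plan$data,
    clean = clean,
    noisy = add_noise(clean, noise_spec(plan$snr_db, plan$seed)),
    file = read_trace_csv(plan$file))
  list(model = model, clean = clean, observed = observed,
       objective = build_objective(model, protocol, observed))
}

run_one <- function(plan, objective, space, run_seed) {
  cfg <- plan$config
  control <- cfg$control %||% trr_control()
  switch(plan$algorithm,
    trr = {
      fit <- with_seed(run_seed, {
        p0 <- random_start(objective, space)
        trr_minimize(objective_residual_fn(objective), p0, space, control)
      })
      list(par = fit$par, cost = fit$cost, termination = fit$termination,
           iterations = fit$iterations)
    },
    pso = {
      fit <- pso_run(objective, space,
                     pso_config(N = cfg$N %||% 24, L = cfg$L %||% 1000,
                                seed = run_seed))
      list(par = fit$best_par, cost = fit$best_cost, termination = "L",
           iterations = cfg$L %||% 1000)
    },
    two_stage = {
      fit <- two_stage_run(objective, space, N = cfg$N %||% 24,
                           L = cfg$L %||% 1000, M = cfg$M %||% 12,
                           seed = run_seed, control = control)
      list(par = fit$best_par, cost = fit$best_cost,
           termination = fit$refinement$table$termination[
             which.min(fit$refinement$table$cost)],
           iterations = cfg$L %||% 1000)
    },
    hybrid = {
      setup <- cfg$setup %||% hybrid_setup("medium")
      if (is.character(setup)) setup <- hybrid_setup(setup)
      fit <- hybrid_run(objective, space, setup, seed = run_seed,
                        final_control = control)
      term <- if (!is.null(fit$refinement)) {
        fit$refinement$table$termination[which.min(fit$refinement$table$cost)]
      } else "L"
      list(par = fit$best_par, cost = fit$best_cost, termination = term,
           iterations = setup$L)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute an experiment plan
#'
#' Runs `n_runs` independent seeded estimations of one experimental cell and
#' summarizes the final-cost distribution. Individual run failures are
#' recorded; the summary is computed over the completed runs (with a
#' warning).
#'
#' @param plan an [experiment_plan()]
#' @param protocol clamp protocol (defaults to [standard_protocol()])
#' @param dir optional directory: run records are appended as JSON lines and
#'   the summary written as CSV
#' @return an object of class `"experiment_result"`: the plan, a data frame
#'   of per-run records (`runs`), the `summary` order statistics, the
#'   termination-reason frequency table, and per-run parameter estimates
#' @export
run_experiment <- function(plan, protocol = standard_protocol(),
                           dir = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  ctx <- plan_objective(plan, protocol)
  space <- make_bounds(ctx$model, plan$width)
  records <- vector("list", plan$n_runs)
  pars <- matrix(NA_real_, plan$n_runs, ctx$model$n_params,
                 dimnames = list(NULL, ctx$model$params$name))
  for (k in seq_len(plan$n_runs)) {
    run_seed <- plan$seed + k
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(run_one(plan, ctx$objective, space, run_seed),
                    error = function(e) list(error = conditionMessage(e)))
    elapsed <- proc.time()[["elapsed"]] - t0
    if (is.null(out$error)) {
      pars[k, ] <- out$par
      # a run whose best cost is +Inf never found a valid vector (possible
      # at degenerate swarm budgets); it has no estimate to re-simulate
      gt_sse <- if (plan$data != "file" && is.finite(out$cost)) {
        fit_trace <- simulate_current(ctx$model, out$par, protocol)
        ground_truth_sse(fit_trace, ctx$clean)
      } else NA_real_
      records[[k]] <- data.frame(run = k, seed = run_seed, cost = out$cost,
                                 gt_sse = gt_sse,
                                 termination = out$termination,
                                 iterations = out$iterations,
                                 elapsed = elapsed, error = NA_character_,
                                 stringsAsFactors = FALSE)
    } else {
      records[[k]] <- data.frame(run = k, seed = run_seed, cost = NA_real_,
                                 gt_sse = NA_real_,
                                 termination = NA_character_,
                                 iterations = NA_integer_, elapsed = elapsed,
                                 error = out$error, stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, records)
  ok <- !is.na(runs$cost)
  if (!all(ok)) {
    warning(sprintf("%d of %d runs failed; summary over completed runs",
                    sum(!ok), plan$n_runs))
  }
  if (!any(ok)) stop("all runs failed")
  result <- structure(list(
    plan = plan, runs = runs,
    summary = distribution_summary(runs$cost[ok]),
    terminations = table(runs$termination[ok]),
    params = pars,
    ground_truth = ctx$clean$meta$ground_truth_params),
    class = "experiment_result")
  if (!is.null(dir)) persist_experiment(result, dir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "%s / %s / %s / %s: n=%d, median cost %.4g [%.4g, %.4g]\n",
    x$plan$current, x$plan$algorithm, x$plan$width, x$plan$data,
    nrow(x$runs), s[["median"]], s[["min"]], s[["max"]]))
  invisible(x)
}

persist_experiment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- with(result$plan, sprintf("%s_%s_%s_%s_seed%d", current, algorithm,
                                    width, data, seed))
  con <- file(file.path(dir, paste0(stem, ".jsonl")), open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(result$runs))) {
    rec <- as.list(result$runs[k, ])
    rec$par <- unname(result$params[k, ])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  utils::write.csv(data.frame(t(result$summary)),
                   file.path(dir, paste0(stem, "_summary.csv")),
                   row.names = FALSE)
  invisible(result)
}

#' Noise-sensitivity study with the dual error metric
#'
#' For each SNR level (plus, optionally, the clean data) and each algorithm,
#' reports both the optimized cost against the (noisy) input trace and the
#' squared error of the fitted model output against the clean ground truth,
#' together with the injected noise energy, which lower-bounds the
#' achievable cost against the noisy input.
#'
#' @param current current id
#' @param snr_db SNR levels in dB
#' @param include_clean also run on the non-noisy data
#' @param algorithms subset of `c("trr", "pso", "two_stage", "hybrid")`
#' @param width search-space width
#' @param n_runs repetitions per cell
#' @param seed master seed
#' @param config per-algorithm configuration (see [experiment_plan()])
#' @param protocol clamp protocol
#' @return data frame with one row per (SNR, algorithm) cell: median cost vs
#'   input, median SSE vs ground truth, and the noise energy of that cell's
#'   input data
#' @export
noise_study <- function(current = "IKr", snr_db = c(10, 20, 35, 60),
                        include_clean = TRUE, algorithms = "trr",
                        width = "wide", n_runs = 5, seed = 1L,
                        config = list(), protocol = standard_protocol()) {
  levels <- c(if (include_clean) NA_real_, snr_db)
  rows <- list()
  for (lev in levels) {
    for (alg in algorithms) {
      plan <- experiment_plan(current, alg, width,
                              data = if (is.na(lev)) "clean" else "noisy",
                              snr_db = if (is.na(lev)) NULL else lev,
                              n_runs = n_runs, seed = seed, config = config)
      ctx <- plan_objective(plan, protocol)
      noise_energy <- if (is.na(lev)) 0
                      else ground_truth_sse(ctx$observed, ctx$clean)
      res <- run_experiment(plan, protocol)
      ok <- !is.na(res$runs$cost)
      rows[[length(rows) + 1L]] <- data.frame(
        current = current, algorithm = alg, snr_db = lev,
        median_cost_vs_input = stats::median(res$runs$cost[ok]),
        median_sse_vs_ground_truth = stats::median(res$runs$gt_sse[ok]),
        noise_energy = noise_energy, n_runs = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Particle-count sweep with log-log median regression
#'
#' Runs the given swarm-based algorithm for each particle count in `N_list`
#' and fits a linear regression of `log10(median cost)` on `log2(N)` (the
#' plotted coordinate system of doubling particle counts on a logarithmic
#' cost axis).
#'
#' @param algorithm `"pso"` or `"two_stage"`
#' @param N_list particle counts (the published sweep doubles N from 24 up
#'   to 12288)
#' @param current,width,n_runs,seed,config,protocol see [experiment_plan()]
#' @param L swarm iterations per run
#' @return list with `summaries` (one [run_experiment()] result per N), a
#'   `table` of medians, and the fitted `regression` (an `lm`)
#' @export
sweep_particles <- function(algorithm = c("pso", "two_stage"),
                            N_list = 24 * 2^(0:3), current = "IKr",
                            width = "narrow", n_runs = 5, L = 200,
                            seed = 1L, config = list(),
                            protocol = standard_protocol()) {
  algorithm <- match.arg(algorithm)
  summaries <- lapply(N_list, function(N) {
    cfg <- utils::modifyList(config, list(N = N, L = L))
    run_experiment(experiment_plan(current, algorithm, width,
                                   n_runs = n_runs, seed = seed,
                                   config = cfg), protocol)
  })
  tab <- data.frame(N = N_list,
                    median = vapply(summaries,
                                    function(s) s$summary[["median"]],
                                    numeric(1)))
  fit <- stats::lm(log10(median) ~ log2(N), data = tab)
  list(summaries = summaries, table = tab, regression = fit)
}

#' Convergence-trace plot of one or more swarm runs
#'
#' Draws the per-iteration global best, median, central quartiles, and
#' min/max of the particle costs, pooled across the supplied runs.
#'
#' @param runs a `"swarm_result"` or list of them
#' @param path optional PDF path; when given the plot is written there
#' @return invisibly, the pooled per-iteration statistics
#' @export
plot_convergence <- function(runs, path = NULL) {
  if (inherits(runs, "swarm_result")) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  conv <- lapply(runs, function(r) r$convergence)
  iter <- conv[[1L]]$iteration
  pool <- function(col) {
    m <- vapply(conv, function(cc) cc[[col]], numeric(length(iter)))
    apply(as.matrix(m), 1L, stats::median)
  }
  stats_df <- data.frame(iteration = iter, best = pool("best"),
                         min = pool("min"), q1 = pool("q1"),
                         median = pool("median"), q3 = pool("q3"),
                         max = pool("max"))
  draw <- function() {
    pos <- stats_df[stats_df$median > 0 & is.finite(stats_df$median), ]
    if (nrow(pos) == 0) stop("no positive finite medians to plot")
    # worst-case envelopes can be +Inf while any particle sits at an
    # invalid vector; the axis range only considers finite positive values
    vals <- unlist(pos[c("min", "max")], use.names = FALSE)
    vals <- vals[is.finite(vals) & vals > 0]
    if (length(vals) == 0) vals <- pos$median
    graphics::plot(pos$iteration, pos$median, type = "l", log = "y",
                   xlab = "iteration", ylab = "SSE [(pA/pF)^2]",
                   ylim = range(vals))
    graphics::polygon(c(pos$iteration, rev(pos$iteration)),
                      c(pmax(pos$q1, .Machine$double.xmin), rev(pos$q3)),
                      col = grDevices::adjustcolor("darkgreen", 0.3),
                      border = NA)
    graphics::lines(pos$iteration, pos$median, lwd = 2)
    graphics::lines(pos$iteration, pmax(pos$min, .Machine$double.xmin),
                    col = "orange")
    graphics::lines(pos$iteration, pos$max, col = "orange")
  }
  if (!is.null(path)) {
    grDevices::pdf(path, width = 7, height = 5)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(stats_df)
}

#' Tables and figures for a set of experiment results
#'
#' Writes a CSV summary table, box plots of the final-cost distributions,
#' and, for runs on synthetic data, plots of the relative deviation of the
#' estimated parameters from the generating values. Convergence traces of
#' individual swarm runs are plotted with [plot_convergence()].
#'
#' @param results list of `"experiment_result"` objects (non-empty)
#' @param dir output directory
#' @return invisibly, the summary table
#' @export
report_experiments <- function(results, dir) {
  if (length(results) == 0) stop("no results to report")
  stopifnot(all(vapply(results, inherits, logical(1), "experiment_result")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(results, function(r) {
    paste(r$plan$current, r$plan$algorithm, r$plan$width, sep = "/")
  }, character(1))
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(current = r$plan$current, algorithm = r$plan$algorithm,
               width = r$plan$width, data = r$plan$data,
               n = sum(!is.na(r$runs$cost)), t(r$summary),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, file.path(dir, "summaries.csv"), row.names = FALSE)

  grDevices::pdf(file.path(dir, "cost_boxplots.pdf"), width = 7, height = 5)
  costs <- lapply(results, function(r) r$runs$cost[!is.na(r$runs$cost)])
  graphics::boxplot(costs, names = labels, log = "y", las = 2,
                    ylab = "final SSE [(pA/pF)^2]")
  grDevices::dev.off()

  for (i in seq_along(results)) {
    r <- results[[i]]
    gt <- r$ground_truth
    if (is.null(gt) || all(is.na(r$params))) next
    dev <- sweep(r$params, 2L, gt, `-`)
    dev <- sweep(dev, 2L, gt, `/`)
    grDevices::pdf(file.path(dir, sprintf("param_deviation_%02d.pdf", i)),
                   width = 8, height = 5)
    graphics::boxplot(as.data.frame(dev), las = 2,
                      ylab = "relative deviation from ground truth",
                      main = labels[i])
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
  }
  invisible(tab)
}
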