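#' Hybrid optimizer setups
#'
#' The three published budget tiers of the per-iteration hybrid -- `low`
#' (K = 5, L = 250, N = 96), `medium` (K = 10, L = 500, N = 192), `high`
#' (K = 20, L = 1000, N = 384) -- plus a `desk` tier (K = 5, L = 60, N = 48,
#' M = 8), a deliberately scaled-down preset for quick interactive runs and
#' test suites; `desk` is not one of the published tiers. `K` is the number
#' of capped trust-region iterations embedded in every swarm iteration, `L`
#' the number of swarm iterations, `N` the particle count, and `M` the
#' number of top-ranked personal bests refined to convergence at the end.
#'
#' @param name one of `"low"`, `"medium"`, `"high"`, `"desk"`
#' @param M final refinement count (defaults to 12 for the published tiers)
#' @return list of class `"hybrid_setup"` with fields `name, K, L, N, M`
#' @export
hybrid_setup <- function(name = c("medium", "low", "high", "desk"),
                         M = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    low = list(K = 5, L = 250, N = 96, M = 12),
    medium = list(K = 10, L = 500, N = 192, M = 12),
    high = list(K = 20, L = 1000, N = 384, M = 12),
    desk = list(K = 5, L = 60, N = 48, M = 8))
  if (!is.null(M)) cfg$M <- M
  stopifnot(cfg$M <= cfg$N)
  structure(c(list(name = name), cfg), class = "hybrid_setup")
}

# refine the first M rows of a ranked position matrix to convergence
final_refine_impl <- function(res_fn, ranked, ranked_costs, bb, M, control) {
  M <- min(M, nrow(ranked))
  pars <- ranked[seq_len(M), , drop = FALSE]
  out_cost <- ranked_costs[seq_len(M)]
  reasons <- character(M)
  iters <- integer(M)
  for (i in seq_len(M)) {
    fit <- tryCatch(trr_minimize(res_fn, pars[i, ], bb, control),
                    error = function(e) NULL)
    if (is.null(fit)) {
      reasons[i] <- "failed"
      next
    }
    if (fit$cost <= out_cost[i] || !is.finite(out_cost[i])) {
      pars[i, ] <- fit$par
      out_cost[i] <- fit$cost
    }
    reasons[i] <- fit$termination
    iters[i] <- fit$iterations
  }
  list(par = pars,
       table = data.frame(rank = seq_len(M), cost = out_cost,
                          pre_cost = ranked_costs[seq_len(M)],
                          termination = reasons, iterations = iters,
                          stringsAsFactors = FALSE))
}

#' Refine the best swarm positions to convergence
#'
#' Runs [trr_minimize()] to convergence from each of the top `M` entries of
#' a ranked list of candidate parameter vectors and reports the improvement
#' over the incoming best (typically small when the swarm has already
#' converged).
#'
#' @param objective a [build_objective()] result (or a function carrying a
#'   `residual_fn` attribute)
#' @param ranked matrix of candidate positions, best first (e.g.
#'   `$personal_bests` of a swarm result)
#' @param space search space
#' @param M number of entries to refine
#' @param control a [trr_control()] for the refinement budget
#' @return list with the refined positions (`par`), a per-entry `table`
#'   (pre/post cost, termination reason), `best_cost`, and the relative
#'   improvement `delta_rel` over the incoming best cost
#' @export
final_refine <- function(objective, ranked, space, M = 12,
                         control = trr_control()) {
  stopifnot(nrow(ranked) >= 1)
  res_fn <- residual_fn_of(objective)
  if (is.null(res_fn)) stop("objective has no residual structure")
  bb <- space_bounds(space)
  costs <- vapply(seq_len(nrow(ranked)),
                  function(i) safe_cost(objective, ranked[i, ]), numeric(1))
  out <- final_refine_impl(res_fn, ranked, costs, bb, M, control)
  pre_best <- min(costs)
  out$best_cost <- min(out$table$cost)
  out$delta_rel <- if (pre_best > 0) (pre_best - out$best_cost) / pre_best
                   else 0
  out
}

#' Sequential two-stage PSO + TRR estimation
#'
#' A full particle swarm run followed by trust-region refinement to
#' convergence of the `M` best distinct personal-best positions; results are
#' ranked by final cost.
#'
#' @inheritParams pso_run
#' @param N,L swarm size and iteration count
#' @param M number of swarm solutions refined by TRR
#' @param seed integer seed (one seed drives both stages)
#' @param control [trr_control()] for the refinement stage
#' @return a `"swarm_result"` whose `refinement` element carries the
#'   per-start TRR outcomes
#' @export
two_stage_run <- function(objective, space, N = 24, L = 1000, M = 12,
                          seed = 1L, control = trr_control()) {
  stopifnot(M <= N)
  swarm <- pso_run(objective, space, pso_config(N = N, L = L, seed = seed))
  res_fn <- residual_fn_of(objective)
  if (is.null(res_fn)) stop("objective has no residual structure")
  bb <- space_bounds(space)
  # distinct personal bests, best first
  keep <- !duplicated(round(swarm$personal_bests, 12))
  ranked <- swarm$personal_bests[keep, , drop = FALSE]
  rcosts <- swarm$personal_best_costs[keep]
  refine <- final_refine_impl(res_fn, ranked, rcosts, bb, M, control)
  ord <- order(refine$table$cost)
  best <- ord[1L]
  swarm$pre_refine_cost <- swarm$best_cost
  swarm$best_par <- refine$par[best, ]
  swarm$best_cost <- refine$table$cost[best]
  swarm$refinement <- refine
  swarm$config$algorithm <- "two_stage"
  swarm$config$M <- M
  swarm
}

#' Per-iteration hybrid (PSO + TRR) optimization
#'
#' In every swarm iteration each particle's boundary-enforced candidate
#' position undergoes up to `K` capped trust-region iterations; the
#' particle's velocity is then redefined as the displacement to the refined
#' position and the particle moves there. Personal and global bests are
#' updated from the refined, costed positions. After `L` iterations the
#' personal bests are sorted by ascending squared error and the best `M`
#' are refined to convergence (the `+ TRR` stage; disable with
#' `final_refine = FALSE`). With `K = 0` the trajectory is identical to
#' [pso_run()] under the same seed.
#'
#' @inheritParams pso_run
#' @param setup a [hybrid_setup()]
#' @param seed integer seed
#' @param final_refine run the terminal TRR stage on the best `M` particles
#' @param inner_control,final_control [trr_control()] for the embedded and
#'   terminal TRR invocations
#' @return a `"swarm_result"`; `$pre_refine_cost` holds the best cost before
#'   the terminal TRR stage
#' @export
hybrid_run <- function(objective, space, setup = hybrid_setup("medium"),
                       seed = 1L, final_refine = TRUE,
                       inner_control = trr_control(),
                       final_control = trr_control()) {
  swarm_engine(objective, space, N = setup$N, L = setup$L, K = setup$K,
               M = if (final_refine) setup$M else 0, seed = seed,
               inner_control = inner_control, final_control = final_control)
}
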