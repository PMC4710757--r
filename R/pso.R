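#' Clerc-Kennedy constriction coefficient
#'
#' `chi = 2 / (phi - 2 + sqrt(phi^2 - 4 phi))` with `phi = phi1 + phi2`,
#' defined for `phi > 4`. With the canonical accelerations
#' `phi1 = phi2 = 2.05`, `chi` is approximately 0.73.
#'
#' @param phi1,phi2 acceleration constants
#' @return the constriction coefficient (dimensionless)
#' @export
constriction_coefficient <- function(phi1 = 2.05, phi2 = 2.05) {
  phi <- phi1 + phi2
  if (phi <= 4) stop("constriction requires phi1 + phi2 > 4")
  2 / (phi - 2 + sqrt(phi^2 - 4 * phi))
}

#' Constriction velocity update
#'
#' `v <- chi * (v + U(0, phi1) * (b_i - p) + U(0, phi2) * (b_g - p))` with
#' fresh per-component uniform draws. Draws come from the caller's RNG
#' stream.
#'
#' @param v current velocity vector
#' @param p current position
#' @param b_i personal best position
#' @param b_g global best position
#' @param chi constriction coefficient
#' @param phi1,phi2 acceleration constants
#' @return the updated velocity vector
#' @export
velocity_update <- function(v, p, b_i, b_g, chi, phi1 = 2.05, phi2 = 2.05) {
  d <- length(p)
  stopifnot(length(v) == d, length(b_i) == d, length(b_g) == d)
  u1 <- stats::runif(d, 0, phi1)
  u2 <- stats::runif(d, 0, phi2)
  chi * (v + u1 * (b_i - p) + u2 * (b_g - p))
}

#' Boundary enforcement with 25% re-randomization
#'
#' Components inside the box are unchanged; a component that crossed a bound
#' is re-drawn uniformly within the 25% of the parameter range adjacent to
#' the crossed bound. Draws come from the caller's RNG stream, in component
#' order.
#'
#' @param candidate proposed position
#' @param space a [make_bounds()] search space or `list(lower, upper)`
#' @return a position within bounds
#' @export
enforce_bounds <- function(candidate, space) {
  bb <- space_bounds(space)
  lower <- bb$lower
  upper <- bb$upper
  w <- upper - lower
  out <- candidate
  for (i in seq_along(out)) {
    if (out[i] < lower[i]) {
      out[i] <- lower[i] + 0.25 * w[i] * stats::runif(1)
    } else if (out[i] > upper[i]) {
      out[i] <- upper[i] - 0.25 * w[i] * stats::runif(1)
    }
  }
  out
}

#' PSO configuration
#'
#' @param N particle count (>= 1)
#' @param L iteration count (>= 1)
#' @param phi1,phi2 acceleration constants (constriction requires
#'   `phi1 + phi2 > 4`)
#' @param seed integer seed making the whole trajectory reproducible
#' @return list of class `"pso_config"`
#' @export
pso_config <- function(N = 24, L = 1000, phi1 = 2.05, phi2 = 2.05,
                       seed = 1L) {
  stopifnot(N >= 1, L >= 1, phi1 + phi2 > 4)
  structure(list(N = N, L = L, phi1 = phi1, phi2 = phi2,
                 seed = as.integer(seed)),
            class = "pso_config")
}

# cost wrapper: +Inf for invalid/failed evaluations
safe_cost <- function(objective, p) {
  if (inherits(objective, "clamp_objective")) return(sse_cost(objective, p))
  val <- tryCatch(objective(p), error = function(e) Inf)
  if (!is.finite(val)) Inf else val
}

# residual function for TRR refinement steps; NULL when the objective is a
# plain cost function without residual structure
residual_fn_of <- function(objective) {
  if (inherits(objective, "clamp_objective")) {
    objective_residual_fn(objective)
  } else if (!is.null(attr(objective, "residual_fn"))) {
    attr(objective, "residual_fn")
  } else {
    NULL
  }
}

# Shared swarm engine for pure PSO (K = 0) and the per-iteration hybrid
# (K >= 1). With identical seeds the K = 0 hybrid reproduces pso_run
# draw-for-draw: the RNG order is, per iteration and particle, the 2*d
# velocity draws followed by one draw per boundary-crossing component, and
# personal/global bests are updated synchronously at the end of each
# iteration.
swarm_engine <- function(objective, space, N, L, K = 0, M = 0,
                         phi1 = 2.05, phi2 = 2.05, seed = 1L,
                         inner_control = trr_control(),
                         final_control = trr_control()) {
  bb <- space_bounds(space)
  lower <- bb$lower
  upper <- bb$upper
  d <- length(lower)
  chi <- constriction_coefficient(phi1, phi2)
  res_fn <- residual_fn_of(objective)
  if (K > 0 && is.null(res_fn)) {
    stop("hybrid refinement needs an objective with residual structure")
  }
  t0 <- proc.time()[["elapsed"]]

  with_seed(seed, {
    P <- matrix(stats::runif(N * d), N, d, byrow = TRUE)
    P <- sweep(sweep(P, 2L, upper - lower, `*`), 2L, lower, `+`)
    V <- matrix(0, N, d)
    costs <- vapply(seq_len(N), function(i) safe_cost(objective, P[i, ]),
                    numeric(1))
    Pb <- P
    pb_cost <- costs
    gbest <- which.min(pb_cost)
    conv <- matrix(NA_real_, L + 1L, 6L)
    colnames(conv) <- c("best", "min", "q1", "median", "q3", "max")
    stats_row <- function(cc, best) {
      fin <- cc[is.finite(cc)]
      if (!length(fin)) return(c(best, rep(Inf, 5)))
      c(best, stats::quantile(fin, c(0, .25, .5, .75, 1), names = FALSE))
    }
    conv[1L, ] <- stats_row(costs, pb_cost[gbest])

    for (it in seq_len(L)) {
      for (i in seq_len(N)) {
        v <- velocity_update(V[i, ], P[i, ], Pb[i, ], Pb[gbest, ], chi,
                             phi1, phi2)
        cand <- enforce_bounds(P[i, ] + v, bb)
        if (K > 0 && is.finite(safe_cost(objective, cand))) {
          ref <- tryCatch(
            trr_step_limited(res_fn, cand, bb, K, inner_control),
            error = function(e) NULL)
          if (!is.null(ref)) cand <- ref$par
        }
        V[i, ] <- cand - P[i, ]
        P[i, ] <- cand
        costs[i] <- safe_cost(objective, P[i, ])
      }
      improved <- costs < pb_cost
      Pb[improved, ] <- P[improved, ]
      pb_cost[improved] <- costs[improved]
      gbest <- which.min(pb_cost)
      conv[it + 1L, ] <- stats_row(costs, pb_cost[gbest])
    }

    ord <- order(pb_cost, seq_len(N)) # stable: ties broken by particle index
    refine <- NULL
    pre_refine_cost <- pb_cost[gbest]
    if (M > 0 && !is.null(res_fn)) {
      refine <- final_refine_impl(res_fn, Pb[ord, , drop = FALSE],
                                  pb_cost[ord], bb, M, final_control)
      Pb[ord[seq_len(nrow(refine$table))], ] <- refine$par
      pb_cost[ord[seq_len(nrow(refine$table))]] <- refine$table$cost
      ord <- order(pb_cost, seq_len(N))
      gbest <- which.min(pb_cost)
    }

    structure(list(
      best_par = Pb[gbest, ], best_cost = pb_cost[gbest],
      pre_refine_cost = pre_refine_cost,
      personal_bests = Pb[ord, , drop = FALSE],
      personal_best_costs = pb_cost[ord],
      particles = P[order(costs, seq_len(N)), , drop = FALSE],
      particle_costs = sort(costs),
      convergence = as.data.frame(cbind(iteration = 0:L, conv)),
      refinement = refine,
      config = list(N = N, L = L, K = K, M = M, phi1 = phi1, phi2 = phi2,
                    seed = seed),
      elapsed = proc.time()[["elapsed"]] - t0),
      class = "swarm_result")
  })
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf(
    "swarm run (N=%d, L=%d, K=%d): best cost %.6g in %.1f s\n",
    x$config$N, x$config$L, x$config$K, x$best_cost, x$elapsed))
  invisible(x)
}

#' Constriction particle swarm optimization
#'
#' Positions are initialized uniformly at random within the search space
#' with zero initial velocities; all initial positions are evaluated before
#' the first velocity update (iteration 0). Each iteration applies the
#' constriction velocity update, moves the particles, re-randomizes
#' boundary-crossing components within the 25% re-entry window, evaluates
#' all costs (a failed or non-finite evaluation scores `+Inf` for that
#' iteration), and updates personal and global bests synchronously. The
#' global-best cost is non-increasing in the iteration index.
#'
#' @param objective a [build_objective()] result, or any function mapping a
#'   parameter vector to a scalar cost
#' @param space a [make_bounds()] search space or `list(lower, upper)`
#' @param config a [pso_config()]
#' @return a `"swarm_result"`: best position and cost, final particles and
#'   personal bests ranked by cost, and the per-iteration convergence trace
#'   (global best plus min/quartiles/median/max of the particle costs)
#' @export
pso_run <- function(objective, space, config = pso_config()) {
  swarm_engine(objective, space, N = config$N, L = config$L, K = 0, M = 0,
               phi1 = config$phi1, phi2 = config$phi2, seed = config$seed)
}
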