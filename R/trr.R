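#' Control settings for the bounded trust-region least-squares solver
#'
#' `ftol` is the minimum absolute decrease of the cost (sum of squared
#' residuals, (pA/pF)^2 for trace objectives) between accepted iterates;
#' `ptol` the minimum Euclidean norm of an accepted parameter step (absolute,
#' in parameter units). Both default to 1e-11. `max_fev` caps residual-vector
#' evaluations (Jacobian columns included) and `max_iter` caps outer
#' iterations (one quadratic model per iteration); `iteration_cap` is the
#' optional hard cap used when the solver runs embedded inside the hybrid
#' optimizer. Jacobians are forward finite differences with relative step
#' `fd_rel_step` (floored at 1% of the box width per parameter).
#'
#' @param ftol minimum cost decrease between accepted iterates
#' @param ptol minimum accepted step norm
#' @param max_iter maximum outer iterations
#' @param max_fev maximum residual evaluations
#' @param iteration_cap optional iteration cap (>= 1) for embedded use
#' @param fd_rel_step relative finite-difference step
#' @return a list of class `"trr_control"`
#' @export
trr_control <- function(ftol = 1e-11, ptol = 1e-11, max_iter = 1e5,
                        max_fev = 5e5, iteration_cap = NULL,
                        fd_rel_step = 1e-8) {
  stopifnot(ftol > 0, ptol > 0, max_iter >= 1, max_fev >= 1,
            is.null(iteration_cap) || iteration_cap >= 1, fd_rel_step > 0)
  structure(list(ftol = ftol, ptol = ptol, max_iter = max_iter,
                 max_fev = max_fev, iteration_cap = iteration_cap,
                 fd_rel_step = fd_rel_step),
            class = "trr_control")
}

space_bounds <- function(space, d = NULL) {
  if (inherits(space, "search_space") || is.data.frame(space)) {
    list(lower = space$lower, upper = space$upper)
  } else if (is.list(space) && !is.null(space$lower)) {
    list(lower = space$lower, upper = space$upper)
  } else {
    stop("space must be a search_space or a list with lower/upper")
  }
}

# forward-difference Jacobian; columns for which both +h and -h fail are zero
fd_jacobian <- function(fn, x, r0, lower, upper, width, rel) {
  d <- length(x)
  J <- matrix(0, length(r0), d)
  nfev <- 0L
  h <- rel * pmax(abs(x), 0.01 * width)
  for (j in seq_len(d)) {
    hj <- h[j]
    if (x[j] + hj > upper[j]) hj <- -hj
    for (attempt in 1:2) {
      xj <- x
      xj[j] <- x[j] + hj
      rj <- tryCatch(fn(xj), error = function(e) NULL)
      nfev <- nfev + 1L
      if (!is.null(rj) && all(is.finite(rj))) {
        J[, j] <- (rj - r0) / hj
        break
      }
      hj <- -hj
      if (x[j] + hj < lower[j] || x[j] + hj > upper[j]) break
    }
  }
  list(J = J, nfev = nfev)
}

# exact solution of min ||Jhat s + r|| s.t. ||s|| <= Delta via the SVD of Jhat
tr_subproblem <- function(sv, r, Delta) {
  b <- -drop(crossprod(sv$u, r))
  dv <- sv$d
  tol <- max(dv) * max(dim(sv$u)) * .Machine$double.eps
  pos <- dv > tol
  coef <- ifelse(pos, b / ifelse(pos, dv, 1), 0)
  s_gn <- drop(sv$v %*% coef)
  if (sqrt(sum(s_gn^2)) <= Delta || all(!pos)) {
    if (sqrt(sum(s_gn^2)) <= Delta) return(s_gn)
  }
  dp <- dv[pos]
  bp <- b[pos]
  nrm <- function(lam) sqrt(sum((dp * bp / (dp^2 + lam))^2))
  hi <- sqrt(sum((dp * bp)^2)) / Delta
  if (!is.finite(hi) || hi <= 0) return(s_gn)
  while (nrm(hi) > Delta) hi <- hi * 2
  lam <- stats::uniroot(function(l) nrm(l) - Delta, c(0, hi),
                        tol = 1e-4 * Delta)$root
  drop(sv$v %*% (dv * b / (dv^2 + lam)))
}

# fraction of step s that stays within the box starting at x
step_to_bound <- function(x, s, lower, upper) {
  frac <- rep(Inf, length(s))
  up <- s > 0
  dn <- s < 0
  frac[up] <- (upper[up] - x[up]) / s[up]
  frac[dn] <- (lower[dn] - x[dn]) / s[dn]
  list(alpha = min(frac, Inf), binding = which(frac <= min(frac) * (1 + 1e-12)))
}

clip_step <- function(x, s, lower, upper, theta = 0.995) {
  sb <- step_to_bound(x, s, lower, upper)
  if (sb$alpha >= 1 / theta) return(s)
  s * max(0, theta * sb$alpha)
}

#' Bounded trust-region-reflective nonlinear least squares
#'
#' Minimizes `sum(residual_fn(p)^2)` within box constraints. Each iteration
#' builds the Gauss-Newton quadratic model of the cost from a forward-
#' difference Jacobian, applies the Coleman-Li scaling implied by the
#' distance of the iterate to its active bounds, solves the trust-region
#' subproblem exactly through an SVD, and evaluates the best of the clipped,
#' reflected, and scaled-gradient candidate steps. Steps are accepted only
#' when they reduce the cost, so the reported iterates descend monotonically
#' and always stay within the bounds. Termination reports exactly one of
#' `pTol` (accepted step norm below `ptol`, or a collapsed trust region),
#' `fTol` (cost decrease below `ftol`), `maxIter`, `maxFunEval`, or
#' `iteration_cap`.
#'
#' @param residual_fn function mapping a parameter vector to the residual
#'   vector; must be finite at `p0`
#' @param p0 start vector (within bounds)
#' @param space a [make_bounds()] search space or `list(lower, upper)`
#' @param control a [trr_control()]
#' @return an object of class `"trr_result"`: `par`, `cost`,
#'   `termination` (string), `iterations`, `nfev`, and `trace` (cost after
#'   each accepted iterate, starting at the initial cost)
#' @export
trr_minimize <- function(residual_fn, p0, space, control = trr_control()) {
  bb <- space_bounds(space)
  lower <- bb$lower
  upper <- bb$upper
  d <- length(p0)
  stopifnot(length(lower) == d, length(upper) == d, all(lower < upper))
  if (any(p0 < lower) || any(p0 > upper)) {
    stop("start vector is outside the bounds")
  }
  width <- upper - lower
  # strictly interior start so the Coleman-Li scaling is well defined
  x <- pmin(pmax(p0, lower + 1e-10 * width), upper - 1e-10 * width)
  r <- residual_fn(x)
  if (!all(is.finite(r))) stop("residuals are not finite at the start vector")
  nfev <- 1L
  cost <- sum(r^2)
  trace <- cost
  Delta <- NULL
  iter <- 0L
  reason <- NULL

  while (is.null(reason)) {
    iter <- iter + 1L
    fd <- fd_jacobian(residual_fn, x, r, lower, upper, width,
                      control$fd_rel_step)
    nfev <- nfev + fd$nfev
    J <- fd$J
    g <- drop(crossprod(J, r))
    v <- ifelse(g < 0, upper - x, x - lower)
    dscl <- sqrt(pmax(v, 1e-12 * pmax(width, 1e-12)))
    Jh <- sweep(J, 2L, dscl, `*`)
    sv <- svd(Jh)
    if (is.null(Delta)) Delta <- max(1, sqrt(sum((x / dscl)^2)))

    accepted <- FALSE
    for (inner in 1:40) {
      shat <- tr_subproblem(sv, r, Delta)
      s_tr <- dscl * shat
      cands <- list(clip_step(x, s_tr, lower, upper))
      sb <- step_to_bound(x, s_tr, lower, upper)
      if (sb$alpha < 1) { # reflect the binding components at the boundary
        s_ref <- s_tr
        s_ref[sb$binding] <- -s_ref[sb$binding]
        s_ref <- sb$alpha * s_tr + (1 - sb$alpha) * s_ref
        cands <- c(cands, list(clip_step(x, s_ref, lower, upper)))
      }
      sd_dir <- -dscl^2 * g # scaled steepest descent, back in x-space
      Jsd <- drop(J %*% sd_dir)
      den <- sum(Jsd^2)
      if (den > 0) {
        tt <- -sum(r * Jsd) / den
        s_sd <- tt * sd_dir
        hn <- sqrt(sum((s_sd / dscl)^2))
        if (hn > Delta) s_sd <- s_sd * (Delta / hn)
        cands <- c(cands, list(clip_step(x, s_sd, lower, upper)))
      }
      preds <- vapply(cands, function(s) {
        Js <- drop(J %*% s)
        -2 * sum(r * Js) - sum(Js^2)
      }, numeric(1))
      best <- which.max(preds)
      s_best <- cands[[best]]
      hat_norm <- sqrt(sum((s_best / dscl)^2))
      if (preds[best] <= 0 || hat_norm == 0) {
        Delta <- Delta / 4
        if (Delta < 1e-13 * max(1, sqrt(sum((x / dscl)^2)))) break
        next
      }
      x_new <- pmin(pmax(x + s_best, lower), upper)
      r_new <- tryCatch(residual_fn(x_new), error = function(e) NULL)
      nfev <- nfev + 1L
      cost_new <- if (is.null(r_new) || !all(is.finite(r_new))) Inf
                  else sum(r_new^2)
      if (cost_new < cost) {
        rho <- (cost - cost_new) / preds[best]
        if (rho < 0.25) {
          Delta <- 0.25 * hat_norm
        } else if (rho > 0.75 && hat_norm >= 0.9 * Delta) {
          Delta <- 2 * Delta
        }
        accepted <- TRUE
        break
      }
      Delta <- 0.25 * min(Delta, hat_norm)
      if (Delta < 1e-13 * max(1, sqrt(sum((x / dscl)^2)))) break
      if (nfev >= control$max_fev) break
    }

    if (accepted) {
      step_norm <- sqrt(sum((x_new - x)^2))
      dcost <- cost - cost_new
      x <- x_new
      r <- r_new
      cost <- cost_new
      trace <- c(trace, cost)
      if (step_norm < control$ptol) {
        reason <- "pTol"
      } else if (dcost < control$ftol) {
        reason <- "fTol"
      }
    } else if (nfev >= control$max_fev) {
      reason <- "maxFunEval"
    } else {
      # trust region collapsed without an acceptable step: no parameter
      # change below ptol is possible any more
      reason <- "pTol"
    }
    if (is.null(reason)) {
      if (!is.null(control$iteration_cap) &&
          iter >= control$iteration_cap) {
        reason <- "iteration_cap"
      } else if (iter >= control$max_iter) {
        reason <- "maxIter"
      } else if (nfev >= control$max_fev) {
        reason <- "maxFunEval"
      }
    }
  }

  structure(list(par = x, cost = cost, termination = reason,
                 iterations = iter, nfev = nfev, trace = trace),
            class = "trr_result")
}

#' @export
print.trr_result <- function(x, ...) {
  cat(sprintf("TRR: cost %.6g after %d iteration(s), %d evaluations (%s)\n",
              x$cost, x$iterations, x$nfev, x$termination))
  invisible(x)
}

#' Run at most K trust-region iterations from a start vector
#'
#' Capped invocation used by the hybrid optimizer: performs up to `K`
#' iterations of [trr_minimize()] and returns the (possibly non-converged)
#' iterate. The returned cost never exceeds the cost at `p0` and the iterate
#' stays within bounds.
#'
#' @inheritParams trr_minimize
#' @param K maximum number of iterations (>= 1)
#' @return a `"trr_result"` (use `$par` for the refined vector)
#' @export
trr_step_limited <- function(residual_fn, p0, space, K,
                             control = trr_control()) {
  stopifnot(K >= 1)
  control$iteration_cap <- K
  trr_minimize(residual_fn, p0, space, control)
}
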