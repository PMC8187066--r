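# Smoothed-L0 solvers.
#
# Both solvers minimize ||theta||_0 through the Gaussian surrogate
#   F_sigma(theta) = sum_i exp(-theta_i^2 / sigma^2),
# maximized over a geometrically decreasing sigma schedule (graduated
# non-convexity). SL0 re-projects each gradient step exactly onto
# {A theta = y}; ReSL0 replaces that with a Tikhonov-regularized
# projection whose strength lambda is chosen adaptively once per outer
# iteration, tolerating measurement error in y.

#' Solver configuration
#'
#' @param rho sigma decay factor per outer iteration, in (0.5, 1). The
#'   default 0.55 anneals fast enough that the relative-change stopping
#'   rule engages only once the iterate has genuinely converged; slow
#'   anneals make the per-iteration change fall under the threshold while
#'   sigma is still large.
#' @param mu inner gradient step size; the inner update is
#'   `theta <- theta - 2 * mu * theta * exp(-theta^2 / sigma^2)`. The
#'   default 1 reproduces the classical SL0 step (step size 2 under the
#'   classical surrogate convention, which carries a 1/2 in the exponent).
#' @param inner_iters gradient-projection steps per sigma value.
#' @param sigma_min_ratio floor for sigma relative to sigma0; a safety
#'   stop alongside the relative-change rule. The default 1e-6 lets the
#'   anneal reach the deep-recovery regime (coefficient errors near the
#'   final sigma scale) that near-exact reconstructions require.
#' @param stop_tol stopping threshold on the relative image change between
#'   outer iterations, `||X_k+1 - X_k|| / ||X_k|| < stop_tol`.
#' @param max_outer cap on outer iterations.
#' @param error_tolerance nominal feasibility slack of the inequality
#'   constraint `||y - A theta|| < delta`; recorded for reporting only
#'   (the regularization lambda is what governs the projection).
#' @param lambda_floor,lambda_cap clipping bounds for the adaptive lambda.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(rho = 0.55, mu = 1, inner_iters = 3,
                          sigma_min_ratio = 1e-6, stop_tol = 0.005,
                          max_outer = 200, error_tolerance = NA_real_,
                          lambda_floor = 1e-16, lambda_cap = 1e16) {
  if (!(rho > 0.5 && rho < 1)) stop_invalid("rho must lie in (0.5, 1)")
  if (mu <= 0) stop_invalid("mu must be positive")
  if (inner_iters < 1) stop_invalid("inner_iters must be >= 1")
  if (!(stop_tol > 0 && stop_tol < 1)) stop_invalid("stop_tol must be in (0, 1)")
  if (sigma_min_ratio <= 0 || sigma_min_ratio >= 1) {
    stop_invalid("sigma_min_ratio must be in (0, 1)")
  }
  if (lambda_floor <= 0 || lambda_cap <= lambda_floor) {
    stop_invalid("need 0 < lambda_floor < lambda_cap")
  }
  structure(
    list(rho = rho, mu = mu, inner_iters = as.integer(inner_iters),
         sigma_min_ratio = sigma_min_ratio, stop_tol = stop_tol,
         max_outer = as.integer(max_outer), error_tolerance = error_tolerance,
         lambda_floor = lambda_floor, lambda_cap = lambda_cap),
    class = "solver_config"
  )
}

#' Gaussian smoothed-L0 surrogate
#'
#' `smoothed_l0_value()` returns `F_sigma(theta) = sum exp(-theta^2/sigma^2)`,
#' which tends to (N - ||theta||_0) as sigma -> 0;
#' `smoothed_l0_gradient()` returns its gradient, component i equal to
#' `(-2 theta_i / sigma^2) exp(-theta_i^2 / sigma^2)`.
#'
#' @param theta numeric vector.
#' @param sigma smoothing width, > 0.
#' @return scalar in (0, N\]; respectively a vector of the same length.
#' @export
smoothed_l0_value <- function(theta, sigma) {
  if (sigma <= 0) stop_invalid("sigma must be positive")
  sum(exp(-theta^2 / sigma^2))
}

#' @rdname smoothed_l0_value
#' @export
smoothed_l0_gradient <- function(theta, sigma) {
  if (sigma <= 0) stop_invalid("sigma must be positive")
  (-2 * theta / sigma^2) * exp(-theta^2 / sigma^2)
}

# One inner gradient-ascent step on F_sigma: theta + mu * sigma^2 * grad.
sl0_gradient_step <- function(theta, sigma, mu) {
  theta - 2 * mu * theta * exp(-theta^2 / sigma^2)
}

#' Exact feasibility projection
#'
#' Euclidean projection onto the affine set `{theta : A theta = y}`:
#' `theta - A^T (A A^T)^-1 (A theta - y)`. The Gram solve truncates
#' numerically-null directions (below 1e-12 of the largest eigenvalue)
#' and iterative-refinement passes keep the relative residual of the
#' output below 1e-8 whenever `A` has full numerical row rank; for a
#' rank-deficient Gram the output matches `y` on its identifiable range
#' (pseudo-inverse semantics). A grossly singular Gram (more than half
#' the directions null) raises a numerical-rank error.
#'
#' @param theta current iterate.
#' @param A a `sensing_op` or plain real matrix with full row rank.
#' @param y measurement vector.
#' @return projected vector.
#' @export
equality_projection <- function(theta, A, y) {
  op <- as_sensing_op(A)
  out <- theta - op$adjoint(op_gram_solve(op, op$forward(theta) - y))
  ny <- sqrt(sum(y^2))
  for (pass in 1:2) {
    r <- op$forward(out) - y
    if (ny == 0 || sqrt(sum(r^2)) <= 1e-9 * ny) break
    out <- out - op$adjoint(op_gram_solve(op, r))
  }
  out
}

#' Tikhonov-regularized feasibility projection
#'
#' The ReSL0 correction step: the minimizer of
#' `||theta_p - theta||^2 + lambda ||A theta_p - y||^2`, evaluated in
#' closed form as `theta - A^T (A A^T + lambda^-1 I)^-1 (A theta - y)`.
#' As lambda -> Inf it reduces to [equality_projection()]; for finite
#' lambda it shrinks, never increases, the residual `||A theta - y||`.
#'
#' @param theta current iterate.
#' @param A a `sensing_op` or plain real matrix.
#' @param y measurement vector.
#' @param lam regularization parameter, > 0.
#' @return corrected vector.
#' @export
regularized_projection <- function(theta, A, y, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || lam <= 0) {
    stop_invalid("lam must be a positive scalar")
  }
  op <- as_sensing_op(A)
  theta - op$adjoint(op_gram_solve(op, op$forward(theta) - y, shift = 1 / lam))
}

#' Adaptive regularization parameter
#'
#' Balances sparsity fit against residual once per outer iteration:
#' `lambda = ||theta_grad - theta_prev||^2 / ||A^T (A theta_grad - y)||^2`,
#' where `theta_grad` is the first inner gradient step at the current
#' sigma and `theta_prev` the iterate the outer iteration started from;
#' the result is clipped to `[floor, cap]`. The ratio grows as the
#' outer iterates approach feasibility, so the damping it applies
#' relaxes toward the exact projection on clean data while measurement
#' noise keeps the residual, and hence the damping, finite. Degenerate
#' cases: zero denominator with nonzero numerator returns `cap` (the
#' point is feasible, no damping needed); both zero returns `floor`.
#'
#' @param theta_grad_step first inner-loop gradient step at this sigma.
#' @param theta_prev iterate from the previous outer iteration.
#' @param A a `sensing_op` or plain real matrix.
#' @param y measurement vector.
#' @param floor,cap positive clipping bounds.
#' @return scalar lambda in `[floor, cap]`.
#' @export
adaptive_lambda <- function(theta_grad_step, theta_prev, A, y,
                            floor = 1e-16, cap = 1e16) {
  stopifnot(length(theta_grad_step) == length(theta_prev), floor > 0, cap > floor)
  op <- as_sensing_op(A)
  num <- sum((theta_grad_step - theta_prev)^2)
  den <- sum(op$adjoint(op$forward(theta_prev) - y)^2)
  if (den == 0) return(if (num == 0) floor else cap)
  min(max(num / den, floor), cap)
}

# Shared solver skeleton for SL0 and ReSL0.
run_smoothed_l0 <- function(op, y, cfg, method) {
  stopifnot(inherits(cfg, "solver_config"))
  if (!all(is.finite(y))) stop_invalid("measurement vector must be finite")
  # The ReSL0 iteration runs on the row-normalized system (the adaptive
  # regularization ratio is not invariant to the overall scale of A and
  # is calibrated at unit Gram scale); the constraint set, and hence the
  # solution, is unchanged. SL0's equality projections are already
  # scale-invariant.
  if (method == "resl0") {
    sc <- op_unit_scaled(op)
    op <- sc$op
    y <- y / sc$scale
  }
  # SL0's equality constraint prescribes a feasible start: the
  # minimum-norm solution. ReSL0's inequality constraint only needs a
  # point near the tolerance ball, and an exactly-interpolating start
  # would zero the residual that the adaptive regularization reads the
  # noise level from, so it starts from a Tikhonov-damped minimum-norm
  # solution (unit shift = the mean Gram eigenvalue of the normalized
  # system).
  theta <- if (method == "resl0") {
    op$adjoint(op_gram_solve(op, y, shift = 1))
  } else {
    op$adjoint(op_gram_solve(op, y))
  }
  sigma0 <- 4 * max(abs(theta))
  make_result <- function(theta, sig_tr, lam_tr, res_tr, n_outer, converged) {
    img <- if (!is.null(op$basis)) synthesize(theta, op$basis) else NULL
    structure(
      list(theta_hat = theta, image_hat = img, method = method,
           sigma_trace = sig_tr, lambda_trace = lam_tr,
           residual_trace = res_tr, n_outer = n_outer,
           converged = converged, config = cfg),
      class = "solver_result"
    )
  }
  if (sigma0 == 0) {   # y = 0: the zero vector is already optimal
    return(make_result(theta, 0, cfg$lambda_floor, 0, 1L, TRUE))
  }
  sigma <- sigma0
  sig_tr <- lam_tr <- res_tr <- numeric(0)
  converged <- FALSE
  j <- 0L
  while (j < cfg$max_outer) {
    j <- j + 1L
    theta_prev <- theta
    if (method == "resl0") {
      theta_grad <- sl0_gradient_step(theta, sigma, cfg$mu)
      lam <- adaptive_lambda(theta_grad, theta_prev, op, y,
                             cfg$lambda_floor, cfg$lambda_cap)
      theta <- regularized_projection(theta_grad, op, y, lam)
      for (l in seq_len(cfg$inner_iters - 1L)) {
        theta <- regularized_projection(sl0_gradient_step(theta, sigma, cfg$mu),
                                        op, y, lam)
      }
    } else {
      lam <- Inf
      for (l in seq_len(cfg$inner_iters)) {
        theta <- equality_projection(sl0_gradient_step(theta, sigma, cfg$mu),
                                     op, y)
      }
    }
    sig_tr[j] <- sigma
    lam_tr[j] <- lam
    res_tr[j] <- sqrt(sum((op$forward(theta) - y)^2))
    denom <- sqrt(sum(theta_prev^2))
    delta <- if (denom > 0) sqrt(sum((theta - theta_prev)^2)) / denom else 0
    if (delta < cfg$stop_tol) {
      converged <- TRUE
      break
    }
    sigma <- cfg$rho * sigma
    if (sigma < cfg$sigma_min_ratio * sigma0) {
      converged <- TRUE
      break
    }
  }
  make_result(theta, sig_tr, lam_tr, res_tr, j, converged)
}

#' Smoothed-L0 solvers
#'
#' `sl0_solve()` runs the baseline SL0 algorithm: minimum-norm
#' initialization, geometric sigma schedule starting at four times the
#' largest initial coefficient magnitude, and inner loops of gradient
#' steps each followed by the exact [equality_projection()].
#' `resl0_solve()` runs the regularized variant: the first gradient step
#' at each sigma fixes the adaptive lambda (see [adaptive_lambda()]),
#' after which the inner loop uses [regularized_projection()] with that
#' lambda. Both stop when the relative change of the iterate between
#' outer iterations drops below `cfg$stop_tol` or the sigma floor is
#' reached; exhausting `max_outer` flags `converged = FALSE`.
#'
#' @param A a `sensing_op` (e.g. from [compose_sensing()]) or plain real
#'   matrix with at least as many columns as rows.
#' @param y real measurement vector (use [real_measurements()] for
#'   complex pressure data).
#' @param cfg a [solver_config()].
#' @return object of class `solver_result` with fields `theta_hat`,
#'   `image_hat` (when the operator carries a basis), `sigma_trace`,
#'   `lambda_trace`, `residual_trace`, `n_outer`, `converged`.
#' @export
sl0_solve <- function(A, y, cfg = solver_config()) {
  run_smoothed_l0(as_sensing_op(A), y, cfg, "sl0")
}

#' @rdname sl0_solve
#' @export
resl0_solve <- function(A, y, cfg = solver_config()) {
  run_smoothed_l0(as_sensing_op(A), y, cfg, "resl0")
}

#' @export
print.solver_result <- function(x, ...) {
  res <- x$residual_trace[length(x$residual_trace)]
  cat(sprintf(
    "<solver_result> %s: %d outer iterations, %sconverged, final residual %.3g\n",
    x$method, x$n_outer, if (x$converged) "" else "NOT ", res
  ))
  invisible(x)
}
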