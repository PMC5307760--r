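#' Simulate a controlled system
#'
#' Integrates the stiff ODE \eqn{\dot x = f(x) + \sum_i g_i(x) u_i(t)} with
#' the implicit-capable `lsoda` solver from \pkg{deSolve}, supplying the
#' system's analytic Jacobian. Integration failure (step-size underflow or
#' non-finite states, typical of an over-aggressive reduction of a stiff
#' model) is signalled as a classed condition `netreduce_blowup` carrying
#' the failure time; callers that score candidate reductions treat it as an
#' infeasibility signal rather than a crash.
#'
#' @param system a [controlled_system()].
#' @param u input: `NULL` (hold the unperturbed input u0), a numeric vector
#'   (constant input), or a function of time returning the input vector.
#' @param x0 initial state (defaults to `system$x0`).
#' @param t_end final time, or `times` an explicit output grid.
#' @param times optional explicit time grid (overrides `t_end`/`n_points`).
#' @param n_points number of output points when only `t_end` is given.
#' @param rtol,atol solver tolerances.
#' @return object of class `trajectory`: list with `times`, `states`
#'   (time x n), `outputs` (time x p).
#' @export
simulate_system <- function(system, u = NULL, x0 = NULL, t_end = NULL,
                            times = NULL, n_points = 201L,
                            rtol = 1e-8, atol = 1e-10) {
  x0 <- x0 %||% system$x0
  if (is.null(times)) {
    assert_that(!is.null(t_end) && t_end > 0, "netreduce_invalid_argument",
                "either times or a positive t_end is required")
    times <- seq(0, t_end, length.out = n_points)
  }
  u_fun <- input_function(system, u)
  n <- system$n
  deriv <- function(t, x, parms) {
    uu <- u_fun(t)
    v <- system$f(x)
    if (length(uu)) v <- v + as_matrix(system$g(x), n) %*% uu
    list(as.numeric(v))
  }
  jacf <- function(t, x, parms) system$jac(x, u_fun(t))
  sol <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = as.numeric(x0), times = times, func = deriv, parms = NULL,
      method = "lsoda", jacfunc = jacf, jactype = "fullusr",
      rtol = rtol, atol = atol
    )),
    error = function(e) e
  )
  if (inherits(sol, "error") || nrow(sol) < length(times) ||
      !all(is.finite(sol[, -1, drop = FALSE]))) {
    t_fail <- if (inherits(sol, "error")) times[1] else {
      bad <- which(apply(!is.finite(sol[, -1, drop = FALSE]), 1L, any))
      sol[if (length(bad)) bad[1] else nrow(sol), 1]
    }
    stopf("netreduce_blowup",
          "integration failed near t = %.4g (stiffness blow-up)", t_fail)
  }
  states <- unname(sol[, -1, drop = FALSE])
  outputs <- t(apply(states, 1L, system$h))
  if (system$p == 1L) outputs <- matrix(outputs, ncol = 1L)
  trajectory(times = times, states = states, outputs = outputs,
             state_names = system$state_names,
             output_names = system$output_names)
}

input_function <- function(system, u) {
  if (is.function(u)) return(u)
  uconst <- if (is.null(u)) system$u0 else as.numeric(u)
  function(t) uconst
}

#' @rdname simulate_system
#' @param states,outputs matrices (rows = time points).
#' @param state_names,output_names column labels.
#' @export
trajectory <- function(times, states, outputs, state_names = NULL,
                       output_names = NULL) {
  structure(list(times = times, states = states, outputs = outputs,
                 state_names = state_names, output_names = output_names),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points, %d states, %d outputs, t in [%g, %g]\n",
              length(x$times), ncol(x$states), ncol(x$outputs),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param traj a trajectory.
#' @param what `"outputs"` or `"states"`.
#' @return data.frame with columns time, variable, value.
#' @export
as_tidy <- function(traj, what = c("outputs", "states")) {
  what <- match.arg(what)
  m <- traj[[what]]
  nm <- (if (what == "outputs") traj$output_names else traj$state_names) %||%
    paste0(substr(what, 1, 1), seq_len(ncol(m)))
  data.frame(
    time = rep(traj$times, ncol(m)),
    variable = rep(nm, each = length(traj$times)),
    value = as.vector(m)
  )
}

#' Locate the unperturbed steady state
#'
#' Integrates the system under the constant unperturbed input `u0` over
#' successively longer horizons until the right-hand side norm stalls, then
#' polishes the estimate with damped Newton iterations using the analytic
#' Jacobian. Signals a classed condition `netreduce_no_steady_state` if the
#' residual cannot be brought below `atol` within `t_max` (e.g. for a
#' limit-cycle system).
#'
#' @param system a [controlled_system()].
#' @param x_guess starting state (defaults to `system$x0`).
#' @param u input held constant (defaults to `u0`).
#' @param atol residual tolerance on the right-hand side norm.
#' @param t_max maximum integration horizon.
#' @return steady-state vector `x*`.
#' @export
find_steady_state <- function(system, x_guess = NULL, u = NULL,
                              atol = 1e-9, t_max = 1e7) {
  x <- as.numeric(x_guess %||% system$x0)
  uu <- if (is.null(u)) system$u0 else as.numeric(u)
  rhs <- rhs_at(system, uu)
  scale <- max(abs(x), 1)
  t_span <- 1
  res_prev <- Inf
  while (t_span <= t_max) {
    traj <- tryCatch(
      simulate_system(system, u = uu, x0 = x, t_end = t_span, n_points = 21L),
      netreduce_blowup = function(e) e
    )
    if (inherits(traj, "error")) break
    x <- traj$states[nrow(traj$states), ]
    res <- sqrt(sum(rhs(x)^2))
    if (res < atol * scale) break
    # Newton polish once the integrator is close
    if (res < 1e-3 * scale) {
      xn <- newton_polish(system, x, uu, atol * scale)
      if (!is.null(xn)) { x <- xn; res <- sqrt(sum(rhs(x)^2)) }
      if (res < atol * scale) break
    }
    if (res > 0.5 * res_prev && res_prev < Inf && t_span > 1e4) break # stalled
    res_prev <- res
    t_span <- t_span * 10
  }
  res <- sqrt(sum(rhs(x)^2))
  # polish only when integration has already closed in on an attractor;
  # a Newton solve from e.g. a limit cycle could land on an unstable root
  if (res < 1e-2 * scale) {
    xn <- newton_polish(system, x, uu, atol * scale)
    if (!is.null(xn) && sqrt(sum(rhs(xn)^2)) < res) {
      x <- xn; res <- sqrt(sum(rhs(x)^2))
    }
  }
  if (res >= atol * scale) {
    stopf("netreduce_no_steady_state",
          "no steady state located (residual %.3g after t = %.3g); the system may not settle under the unperturbed input",
          res, min(t_span, t_max))
  }
  x
}

newton_polish <- function(system, x, u, tol, max_iter = 25L) {
  rhs <- rhs_at(system, u)
  for (it in seq_len(max_iter)) {
    r <- rhs(x)
    if (sqrt(sum(r^2)) < tol) return(x)
    J <- system$jac(x, u)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      if (sqrt(sum(rhs(xn)^2)) < sqrt(sum(r^2)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (sqrt(sum(rhs(xn)^2)) >= sqrt(sum(r^2))) return(x)
    x <- xn
  }
  x
}

#' Maximal relative output error between two trajectories
#'
#' The reduction-quality metric: pointwise relative error
#' \eqn{\epsilon_i(t) = |y_i(t) - \bar y_i(t)| / |y_i(t)|} on the reference
#' time grid (the candidate is resampled by monotone cubic interpolation),
#' with a denominator guard masking time points where
#' \eqn{|y_i(t)| < \delta \max_t |y_i(t)|}; E is the supremum over
#' unmasked points. The guard keeps E finite for outputs that start at or
#' cross zero while leaving the metric untouched elsewhere.
#'
#' @param reference,candidate `trajectory` objects with equal output
#'   dimension.
#' @param delta guard fraction (default 1e-3).
#' @return object of class `error_report`: list with `E` (the maximal
#'   relative error, dimensionless), `pointwise` (time x p matrix of
#'   \eqn{\epsilon_i(t)}, NA where guarded) and `guard_mask`.
#' @export
max_relative_error <- function(reference, candidate, delta = 1e-3) {
  Y <- reference$outputs
  p <- ncol(Y)
  assert_that(ncol(candidate$outputs) == p, "netreduce_invalid_argument",
              "trajectories have different output dimensions")
  Yb <- vapply(seq_len(p), function(i)
    interp_col(candidate$times, candidate$outputs[, i], reference$times),
    numeric(length(reference$times)))
  Yb <- matrix(Yb, ncol = p)
  guard <- matrix(FALSE, nrow(Y), p)
  eps <- matrix(NA_real_, nrow(Y), p)
  for (i in seq_len(p)) {
    thr <- delta * max(abs(Y[, i]))
    ok <- abs(Y[, i]) > thr
    guard[, i] <- !ok
    eps[ok, i] <- abs(Y[ok, i] - Yb[ok, i]) / abs(Y[ok, i])
  }
  if (!any(!guard)) {
    stopf("netreduce_degenerate_output",
          "all time points guarded: reference output is identically ~0")
  }
  structure(list(E = max(eps, na.rm = TRUE), pointwise = eps,
                 guard_mask = guard, delta = delta),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> E = %.4g (%.3g%%), %d/%d points guarded\n",
              x$E, 100 * x$E, sum(x$guard_mask), length(x$guard_mask)))
  invisible(x)
}

#' Stiffness coefficient
#'
#' The ratio of the largest to the smallest Jacobian eigenvalue magnitude
#' at a reference state, \eqn{\chi = \max_i |\lambda_i| / \min_i
#' |\lambda_i|}. Eigenvalues with modulus below `eps_rank` times the
#' largest are excluded: exact conservation relations contribute zero
#' eigenvalues that would make the ratio infinite, which is why the
#' coefficient is normally quoted for the conservation-eliminated
#' realisation.
#'
#' @param system a [controlled_system()].
#' @param x state at which to evaluate the Jacobian (default `x0`).
#' @param u input (default `u0`).
#' @param eps_rank relative modulus threshold for exclusion.
#' @return the dimensionless stiffness coefficient.
#' @export
stiffness_coefficient <- function(system, x = NULL, u = NULL, eps_rank = 1e-9) {
  x <- x %||% system$x0
  uu <- if (is.null(u)) system$u0 else u
  J <- system$jac(x, uu)
  assert_that(all(is.finite(J)), "netreduce_invalid_argument",
              "Jacobian is not finite at the requested state")
  lam <- Mod(eigen(J, only.values = TRUE)$values)
  keep <- lam > eps_rank * max(lam)
  if (!any(keep)) {
    stopf("netreduce_undefined_stiffness",
          "all Jacobian eigenvalues are numerically zero; stiffness undefined")
  }
  lam <- lam[keep]
  max(lam) / min(lam)
}
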