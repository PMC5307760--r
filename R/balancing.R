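#' Perturbation design for empirical Gramians
#'
#' Describes the family of perturbed simulations from which the empirical
#' controllability and observability Gramians are assembled: multipliers
#' applied to the reference input magnitude (controllability) and to the
#' components of the initial condition (observability), a simulation
#' horizon, and the output grid used for trapezoidal quadrature.
#' Multipliers are sampled uniformly on `range` (0.2-1.8 of the
#' unperturbed value by default) under the given seed.
#'
#' @param n_sims number of sampled perturbation magnitudes per direction.
#' @param range multiplier range, uniform sampling.
#' @param horizon simulation horizon (time units of the system); if `NULL`
#'   a settle time is estimated from the Jacobian at the steady state.
#' @param n_points quadrature grid size.
#' @param seed integer seed making the design reproducible.
#' @param fallback_scale additive perturbation scale used for a state
#'   whose steady-state value is zero (a multiplicative perturbation of
#'   zero would never excite it).
#' @return object of class `perturbation_design`.
#' @export
perturbation_design <- function(n_sims = 10L, range = c(0.2, 1.8),
                                horizon = NULL, n_points = 201L,
                                seed = 1L, fallback_scale = 1) {
  assert_that(all(range > 0) && diff(range) >= 0, "netreduce_invalid_argument",
              "multiplier range must be positive and increasing")
  structure(list(n_sims = as.integer(n_sims), range = range,
                 horizon = horizon, n_points = as.integer(n_points),
                 seed = as.integer(seed), fallback_scale = fallback_scale),
            class = "perturbation_design")
}

design_multipliers <- function(design) {
  set.seed(design$seed)
  stats::runif(design$n_sims, design$range[1], design$range[2])
}

# Horizon: time for the slowest retained mode to decay to ~1e-4.
default_horizon <- function(system, x_star) {
  J <- system$jac(x_star, system$u0)
  re <- Re(eigen(J, only.values = TRUE)$values)
  decay <- -re[re < -1e-12]
  if (!length(decay)) return(100)
  min(9.2 / min(decay), 1e6)   # log(1e4) / slowest decay rate
}

#' Empirical controllability Gramian
#'
#' Assembles the controllability Gramian from impulse-type perturbations
#' of each input channel: for every sampled magnitude c the state is
#' kicked from the unperturbed steady state x* along the channel
#' direction g_i(x*), the free response is simulated, and the
#' quadrature-weighted outer products of the state deviations from x*
#' are averaged with weight 1/c^2 across magnitudes and channels. For a
#' stable linear system this construction converges to the Lyapunov
#' controllability Gramian; for a nonlinear system it averages the
#' locally reachable directions over the sampled perturbation strengths.
#' Conserved totals are re-derived from each perturbed full-model initial
#' condition through the system's `from_full` hook, so perturbations
#' remain consistent with conservation.
#'
#' @param system a [controlled_system()] (typically conservation-reduced
#'   and lumped).
#' @param design a [perturbation_design()].
#' @param x_star unperturbed steady state (located if omitted).
#' @return n x n symmetric positive semi-definite matrix.
#' @export
empirical_controllability_gramian <- function(system, design = perturbation_design(),
                                              x_star = NULL) {
  x_star <- x_star %||% find_steady_state(system)
  n <- system$n
  l <- max(1L, system$l)
  G0 <- as_matrix(system$g(x_star), n)
  mult <- design_multipliers(design)
  horizon <- design$horizon %||% default_horizon(system, x_star)
  times <- seq(0, horizon, length.out = design$n_points)
  P <- matrix(0, n, n)
  n_used <- 0L
  for (i in seq_len(l)) {
    dir <- G0[, i]
    if (max(abs(dir)) == 0) next   # disconnected input channel
    u_ref <- if (length(system$u0) >= i && abs(system$u0[i]) > 0)
      abs(system$u0[i]) else 1
    for (m in mult) {
      cc <- m * u_ref
      if (abs(cc) < 1e-12) next
      x0p <- perturbed_initial(system, x_star, cc * dir)
      sysp <- x0p$system
      traj <- tryCatch(
        simulate_system(sysp, u = system$u0, x0 = x0p$x0, times = times),
        netreduce_blowup = function(e)
          stopf("netreduce_gramian_failure",
                "controllability simulation blew up (channel %d, multiplier %.3g): %s",
                i, m, conditionMessage(e))
      )
      dev <- sweep(traj$states, 2L, x_star)
      P <- P + gramian_quadrature(times, dev, dev) / cc^2
      n_used <- n_used + 1L
    }
  }
  if (n_used > 0L) P <- P / n_used
  (P + t(P)) / 2
}

#' Empirical observability Gramian
#'
#' Assembles the observability Gramian from perturbations of the initial
#' condition: each state component j is perturbed multiplicatively about
#' the unperturbed steady state (additively with the design's fallback
#' scale when that component's steady state is zero), the output response
#' is recorded, and Q is built from the quadrature of the outer products
#' of output deviations with weight 1/(c_j c_k). Before every simulation
#' the conserved totals are recomputed from the perturbed full-model
#' initial condition via `from_full`, so no perturbation violates
#' conservation. For a stable linear system the construction converges to
#' the Lyapunov observability Gramian.
#'
#' @inheritParams empirical_controllability_gramian
#' @return n x n symmetric positive semi-definite matrix.
#' @export
empirical_observability_gramian <- function(system, design = perturbation_design(),
                                            x_star = NULL) {
  x_star <- x_star %||% find_steady_state(system)
  n <- system$n
  mult <- design_multipliers(design)
  horizon <- design$horizon %||% default_horizon(system, x_star)
  times <- seq(0, horizon, length.out = design$n_points)
  y_star <- system$h(x_star)
  Q <- matrix(0, n, n)
  n_used <- 0L
  for (m in mult) {
    # deviation magnitude per state: multiplicative about x*, additive
    # fallback where x*_j = 0
    c_j <- ifelse(abs(x_star) > 1e-12 * max(abs(x_star), 1),
                  (m - 1) * x_star, (m - 1) * design$fallback_scale)
    if (all(abs(c_j) < 1e-12)) next   # m ~ 1 excites nothing
    dev_y <- vector("list", n)
    ok <- rep(TRUE, n)
    for (j in seq_len(n)) {
      x0p <- perturbed_initial(system, x_star, c_j[j] * unit_vec(n, j))
      traj <- tryCatch(
        simulate_system(x0p$system, u = system$u0, x0 = x0p$x0, times = times),
        netreduce_blowup = function(e)
          stopf("netreduce_gramian_failure",
                "observability simulation blew up (state %d, multiplier %.3g): %s",
                j, m, conditionMessage(e))
      )
      dev_y[[j]] <- sweep(traj$outputs, 2L, y_star)
    }
    for (j in seq_len(n)) {
      for (k in j:n) {
        q <- gramian_quadrature(times, dev_y[[j]], dev_y[[k]])
        val <- sum(diag(as.matrix(q))) / (c_j[j] * c_j[k])
        Q[j, k] <- Q[j, k] + val
        if (k > j) Q[k, j] <- Q[k, j] + val
      }
    }
    n_used <- n_used + 1L
  }
  if (n_used > 0L) Q <- Q / n_used
  (Q + t(Q)) / 2
}

# trapezoid quadrature of A(t)^T-outer-products: sum_t w_t a_t b_t^T
gramian_quadrature <- function(times, A, B) {
  nt <- length(times)
  w <- c(diff(times)[1] / 2,
         (diff(times)[-1] + diff(times)[-(nt - 1L)]) / 2,
         diff(times)[nt - 1L] / 2)
  t(A * w) %*% B
}

unit_vec <- function(n, j) { e <- numeric(n); e[j] <- 1; e }

# Apply a deviation in current coordinates and re-derive conserved totals
# from the corresponding full-model initial condition.
perturbed_initial <- function(system, x_star, delta) {
  x_full <- system$lift(x_star + delta)
  sysp <- system$from_full(x_full)
  list(system = sysp, x0 = sysp$x0)
}

#' Balancing transformation (Laub's square-root method)
#'
#' Computes the balancing projection from Cholesky factors of the
#' Gramians: with \eqn{P = Lc' Lc} and \eqn{Q = Rc' Rc}, the SVD
#' \eqn{Lc Rc' = U \Sigma V'} yields the Hankel singular values (the
#' diagonal of \eqn{\Sigma}) and the projection pair
#' \eqn{T_1 = \Sigma_1^{-1/2} V_1' Rc}, \eqn{S_1 = Lc' U_1
#' \Sigma_1^{-1/2}}, which makes both transformed Gramians equal to
#' \eqn{diag(\Sigma_1)}. Semi-definite Gramians are factorised by a
#' rank-revealing pivoted Cholesky, so an exactly singular direction
#' shows up as a zero Hankel value rather than being masked.
#'
#' @param P,Q symmetric PSD Gramians of equal dimension.
#' @param n_red retained dimension (default: full numerical rank).
#' @return object of class `balancing_transform`: list with `T1`
#'   (n_red x n), `S1` (n x n_red), `hankel` (all Hankel singular
#'   values, non-increasing), `n_red`, and the Cholesky factors.
#' @export
balancing_transform <- function(P, Q, n_red = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  assert_that(all(dim(P) == c(n, n)) && all(dim(Q) == c(n, n)),
              "netreduce_invalid_argument", "P and Q must be square, equal size")
  assert_that(max(abs(P - t(P))) <= 1e-8 * max(abs(P), 1) &&
                max(abs(Q - t(Q))) <= 1e-8 * max(abs(Q), 1),
              "netreduce_invalid_argument", "P and Q must be symmetric")
  Lc <- ridge_chol(P)
  Rc <- ridge_chol(Q)
  sv <- svd(Lc %*% t(Rc))
  hankel <- sv$d
  rank <- sum(hankel > 1e-12 * max(hankel, .Machine$double.eps))
  n_red <- n_red %||% rank
  if (n_red > rank) {
    stopf("netreduce_rank_error",
          "requested n_red = %d exceeds the numerical Hankel rank %d; the largest feasible reduced dimension is %d",
          n_red, rank, rank)
  }
  s1 <- hankel[seq_len(n_red)]
  V1 <- sv$v[, seq_len(n_red), drop = FALSE]
  U1 <- sv$u[, seq_len(n_red), drop = FALSE]
  T1 <- diag(1 / sqrt(s1), n_red) %*% t(V1) %*% Rc
  S1 <- t(Lc) %*% U1 %*% diag(1 / sqrt(s1), n_red)
  structure(list(T1 = T1, S1 = S1, hankel = hankel, n_red = n_red,
                 chol_P = Lc, chol_Q = Rc),
            class = "balancing_transform")
}

ridge_chol <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  # semi-definite: pivoted, rank-revealing factorisation
  chp <- tryCatch(suppressWarnings(chol(M, pivot = TRUE)),
                  error = function(e) NULL)
  if (!is.null(chp)) {
    r <- attr(chp, "rank")
    U <- chp[, order(attr(chp, "pivot")), drop = FALSE]
    if (r < nrow(M)) U[(r + 1L):nrow(M), ] <- 0
    if (max(abs(t(U) %*% U - M)) <= 1e-8 * max(abs(M), .Machine$double.eps)) {
      return(U)
    }
  }
  stopf("netreduce_invalid_argument",
        "Gramian is not positive semi-definite")
}

#' @export
print.balancing_transform <- function(x, ...) {
  cat(sprintf("<balancing_transform> n = %d -> n_red = %d; hankel: %s\n",
              ncol(x$T1), x$n_red,
              paste(signif(utils::head(x$hankel, 6L), 3), collapse = ", ")))
  invisible(x)
}

#' Truncate a system through a balancing transformation
#'
#' Applies the Galerkin projection with (T1, S1): the balanced directions
#' with the smallest Hankel singular values are discarded, retaining the
#' `n_red` directions that dominate the input-output map. Because the
#' empirical Gramians measure deviations about the unperturbed steady
#' state, the projection is applied to deviation variables centred on
#' `x_center` (default: the steady state used for the Gramians, falling
#' back to the origin); the centre then remains an exact fixed point of
#' the truncated dynamics.
#'
#' @param system a [controlled_system()].
#' @param transform a [balancing_transform()].
#' @param n_red optionally truncate further than the transform's own
#'   `n_red` (uses the leading rows/columns).
#' @param x_center projection centre (length n); default origin.
#' @return a [controlled_system()] of dimension `n_red`.
#' @export
truncate_balanced <- function(system, transform, n_red = NULL,
                              x_center = NULL) {
  n_red <- n_red %||% transform$n_red
  assert_that(n_red <= transform$n_red, "netreduce_invalid_argument",
              "n_red exceeds the transform's retained dimension")
  T1 <- transform$T1[seq_len(n_red), , drop = FALSE]
  S1 <- transform$S1[, seq_len(n_red), drop = FALSE]
  galerkin_reduce(system, T1, S1,
                  state_names = paste0("b", seq_len(n_red)),
                  center = x_center)
}

#' Empirical controllability/observability importance indices
#'
#' Per-state indices from the square roots of the Gramian diagonals,
#' rescaled so the maximum of each vector is exactly 1:
#' \eqn{\nu_{o,i} = \sqrt{Q_{ii}} / \max_j \sqrt{Q_{jj}}} (observability),
#' \eqn{\nu_{c,i} = \sqrt{P_{ii}} / \max_j \sqrt{P_{jj}}}
#' (controllability), and the input-output importance index
#' \eqn{\nu_i = \nu_{o,i}\nu_{c,i} / \max_j (\nu_{o,j}\nu_{c,j})}. A zero
#' index means the state neither responds to the input nor influences the
#' output.
#'
#' @param P,Q empirical Gramians (same dimension).
#' @param labels state/lump names.
#' @return data.frame with columns `state`, `controllability`,
#'   `observability`, `input_output`.
#' @export
importance_indices <- function(P, Q, labels = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  dP <- sqrt(pmax(diag(P), 0))
  dQ <- sqrt(pmax(diag(Q), 0))
  if (max(dP) == 0 && max(dQ) == 0) {
    stopf("netreduce_undefined_index",
          "both Gramians are zero; importance indices undefined")
  }
  nu_c <- if (max(dP) > 0) dP / max(dP) else dP
  nu_o <- if (max(dQ) > 0) dQ / max(dQ) else dQ
  prod <- nu_c * nu_o
  nu <- if (max(prod) > 0) prod / max(prod) else prod
  data.frame(state = labels %||% paste0("x", seq_along(nu)),
             controllability = nu_c, observability = nu_o,
             input_output = nu)
}
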